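## Unit system shared by the molecular and continuum halves of the model.
##
## Internal molecular units are nm / Da / kJ·mol^-1; the derived time unit
## sqrt(Da nm^2 / (kJ/mol)) is exactly 1 ps, so velocities are nm/ps and the
## MD force unit is kJ·mol^-1·nm^-1.  The finite element half works in
## nm / nN / GPa (1 GPa = 1 nN/nm^2).  Conversions are applied only at the
## coupling boundary and for reporting.

#' Physical constants
#'
#' Avogadro's number and the Boltzmann constant in internal molecular units.
#'
#' @format A named list with elements `N_A` (mol^-1), `k_B`
#'   (kJ mol^-1 K^-1), and `force_pN` (pN per kJ mol^-1 nm^-1).
#' @export
ss_constants <- list(
  N_A      = 6.02214076e23,
  k_B      = 0.0083144626,
  ## 1 kJ/mol/nm = 1000 J / (N_A * 1e-9 m) = 1.66054e-12 N
  force_pN = 1000 / (6.02214076e23 * 1e-9) / 1e-12
)

## Registry of supported units: SI scale factor and dimension exponents over
## (m, kg, s, K).  "per mole" quantities are treated as counts, i.e. the
## mole is absorbed into the scale via Avogadro's number, which is what makes
## kJ/mol/nm and pN commensurable.
.unit_registry <- local({
  NA_  <- 6.02214076e23
  dim_ <- function(m = 0, kg = 0, s = 0, K = 0) c(m = m, kg = kg, s = s, K = K)
  u <- function(scale, dims) list(scale = scale, dims = dims)
  list(
    ## length
    "nm"  = u(1e-9,  dim_(m = 1)),
    "um"  = u(1e-6,  dim_(m = 1)),
    "m"   = u(1,     dim_(m = 1)),
    ## time
    "fs"  = u(1e-15, dim_(s = 1)),
    "ps"  = u(1e-12, dim_(s = 1)),
    "ns"  = u(1e-9,  dim_(s = 1)),
    "s"   = u(1,     dim_(s = 1)),
    ## mass
    "Da"  = u(1e-3 / NA_, dim_(kg = 1)),
    "kg"  = u(1,          dim_(kg = 1)),
    ## temperature
    "K"   = u(1, dim_(K = 1)),
    ## energy
    "kJ/mol" = u(1e3 / NA_, dim_(m = 2, kg = 1, s = -2)),
    "J"      = u(1,         dim_(m = 2, kg = 1, s = -2)),
    ## force
    "kJ/mol/nm" = u(1e3 / NA_ / 1e-9, dim_(m = 1, kg = 1, s = -2)),
    "pN"        = u(1e-12,            dim_(m = 1, kg = 1, s = -2)),
    "nN"        = u(1e-9,             dim_(m = 1, kg = 1, s = -2)),
    "N"         = u(1,                dim_(m = 1, kg = 1, s = -2)),
    ## spring stiffness (force per length)
    "kJ/mol/nm^2" = u(1e3 / NA_ / 1e-18, dim_(kg = 1, s = -2)),
    "pN/nm"       = u(1e-12 / 1e-9,      dim_(kg = 1, s = -2)),
    "nN/nm"       = u(1e-9 / 1e-9,       dim_(kg = 1, s = -2)),
    "N/m"         = u(1,                 dim_(kg = 1, s = -2)),
    ## pressure / modulus
    "GPa"     = u(1e9, dim_(m = -1, kg = 1, s = -2)),
    "Pa"      = u(1,   dim_(m = -1, kg = 1, s = -2)),
    "nN/nm^2" = u(1e-9 / 1e-18, dim_(m = -1, kg = 1, s = -2)),
    ## velocity
    "m/s"   = u(1,            dim_(m = 1, s = -1)),
    "nm/ps" = u(1e-9 / 1e-12, dim_(m = 1, s = -1)),
    "nm/ns" = u(1e-9 / 1e-9,  dim_(m = 1, s = -1)),
    ## loading rate
    "pN/s"  = u(1e-12, dim_(m = 1, kg = 1, s = -3)),
    "nN/ns" = u(1e-9 / 1e-9, dim_(m = 1, kg = 1, s = -3))
  )
})

#' Convert between the model's physical units
#'
#' Applies the exact scale factor between two units from the package's fixed
#' registry. Molar and absolute mechanical units are commensurable: the mole
#' is absorbed via Avogadro's number, so e.g. `kJ/mol/nm` converts to `pN`.
#'
#' @param value numeric vector of quantities expressed in `from`.
#' @param from,to unit names; see Details for the supported set.
#' @details Supported units: length (`nm`, `um`, `m`), time (`fs`, `ps`,
#'   `ns`, `s`), mass (`Da`, `kg`), temperature (`K`), energy (`kJ/mol`,
#'   `J`), force (`kJ/mol/nm`, `pN`, `nN`, `N`), stiffness (`kJ/mol/nm^2`,
#'   `pN/nm`, `nN/nm`, `N/m`), modulus (`GPa`, `Pa`, `nN/nm^2`), velocity
#'   (`m/s`, `nm/ps`, `nm/ns`) and loading rate (`pN/s`, `nN/ns`).
#'   Dimensionally incompatible pairs are rejected.
#' @return numeric vector in units of `to`.
#' @examples
#' ss_convert(1, "kJ/mol/nm", "pN")   # ~1.6605
#' ss_convert(0.28, "nN/nm", "kJ/mol/nm^2")
#' @export
ss_convert <- function(value, from, to) {
  uf <- .unit_registry[[from]]
  ut <- .unit_registry[[to]]
  if (is.null(uf)) stop("unknown unit: '", from, "'", call. = FALSE)
  if (is.null(ut)) stop("unknown unit: '", to, "'", call. = FALSE)
  if (!identical(uf$dims, ut$dims)) {
    stop("incompatible dimensions: cannot convert '", from, "' to '", to, "'",
         call. = FALSE)
  }
  value * (uf$scale / ut$scale)
}

## Fixed conversion factors used at the MD<->FEM boundary.
## MD forces (kJ/mol/nm) -> FEM forces (nN), and back for stiffnesses.
.md_force_to_nN <- 1000 / (6.02214076e23 * 1e-9) / 1e-9
.nN_per_nm_to_md <- 1 / .md_force_to_nN  # nN/nm -> kJ/mol/nm^2
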