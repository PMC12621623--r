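## Coarse-grained spatula bead networks and the frozen substrate.
##
## A spatula is a jittered-lattice fill of a parametric shape: a thin pad
## plate with a tapered distal tip strip, and a cylindrical shaft rising
## from the proximal pad end at 45 degrees (the natural inclination of the
## final seta branches). Every bead is bonded to its 30 nearest neighbours
## with anisotropic harmonic springs whose stiffness increases for bonds
## aligned with the keratin fibril direction (the shaft axis).

#' Anisotropic harmonic bond stiffness
#'
#' `K = k + k_b * |cos(theta)|` where `theta` is the angle between the bond
#' vector and the keratin fibril direction.
#'
#' @param bond_vec bond vector (length-3 numeric), any units.
#' @param fibril fibril direction vector (length-3 numeric).
#' @param k base isotropic force constant.
#' @param k_b additional force constant along the fibril direction.
#' @return stiffness `K` in the units of `k`.
#' @export
bond_stiffness <- function(bond_vec, fibril, k, k_b) {
  nb <- sqrt(sum(bond_vec^2)); nf <- sqrt(sum(fibril^2))
  if (nb == 0 || nf == 0)
    stop("zero-length vector in bond_stiffness", call. = FALSE)
  k + k_b * abs(sum(bond_vec * fibril)) / (nb * nf)
}

#' Spatula shape presets
#'
#' Dimensions (nm) of the parametric spatula shape. `"mini"` is the reduced
#' desk-scale model used by the test fixtures; `"full"` approximates the
#' full-scale spatula footprint.
#'
#' @param preset `"mini"` or `"full"`.
#' @return named list of dimensions: `pad_L`, `pad_W`, `pad_T` (pad plate
#'   length/width/thickness), `tip_len` (distal tip strip length),
#'   `shaft_R` (shaft radius), `shaft_L` (shaft length along its axis), and
#'   the default `spacing` (bead lattice spacing).
#' @export
spatula_dims <- function(preset = c("mini", "full")) {
  preset <- match.arg(preset)
  switch(preset,
    mini = list(pad_L = 60, pad_W = 36, pad_T = 10, tip_len = 12,
                shaft_R = 10, shaft_L = 85, spacing = 5, jitter = 0.2),
    ## full-scale spacing/jitter calibrated so the bond-length statistics
    ## match the reference network (shortest ~3 nm, mean ~7.3 nm)
    full = list(pad_L = 300, pad_W = 200, pad_T = 15, tip_len = 40,
                shaft_R = 25, shaft_L = 400, spacing = 4.4, jitter = 0.18))
}

## local frame: pad plate top face at y = 0 spanning x in [-pad_L, shaft_R],
## z in [-W/2, W/2], thickness downward; shaft axis rises from the origin
## along u = (1, 1, 0)/sqrt(2). The distal tip strip is the thin bottom
## layer at the far (-x) end.
.shaft_axis <- c(1, 1, 0) / sqrt(2)

#' Build a coarse-grained spatula model
#'
#' Fills the parametric spatula shape with beads on a jittered lattice,
#' labels regions (tip / pad / shaft), and bonds every bead to its 30
#' nearest neighbours (symmetrised), with equilibrium lengths equal to the
#' as-built distances and anisotropic stiffness from [bond_stiffness()].
#'
#' @param dims shape dimensions, see [spatula_dims()].
#' @param spacing bead lattice spacing in nm (default from `dims`).
#' @param jitter uniform jitter amplitude as a fraction of `spacing`.
#' @param k base bond force constant, nN/nm. The default 0.28 equals the
#'   anchor-point (MD-coupling) spring constant.
#' @param k_b additional fibril-direction force constant, nN/nm.
#' @param mass bead mass in Da (about five keratin molecules).
#' @param n_neighbours number of nearest neighbours each bead bonds to.
#' @param seed integer seed for the jitter.
#' @return object of class `spatula_model`: list with `pos` (n x 3 matrix,
#'   nm, local frame), `region` (factor tip/pad/shaft), `bonds` (tibble:
#'   i, j, b0, K with K in internal kJ/mol/nm^2), `fibril` (unit vector),
#'   `mass` (Da), `k`/`k_b` (nN/nm), `volume` (nm^3), bond-length summary.
#' @export
build_spatula <- function(dims = spatula_dims("mini"), spacing = NULL,
                          jitter = NULL, k = 0.28, k_b = 0.14,
                          mass = 65228, n_neighbours = 30, seed = 1L) {
  if (is.null(spacing)) spacing <- dims$spacing
  if (is.null(jitter)) jitter <- dims$jitter %||% 0.2
  stopifnot(spacing > 0, jitter >= 0, jitter < 0.5, k > 0, k_b >= 0)
  rng <- .seeded_rng(seed); on.exit(rng$restore())

  a <- spacing
  grid1 <- function(lo, hi) {
    n <- max(1L, floor((hi - lo) / a))
    lo + (hi - lo - (n - 1) * a) / 2 + (seq_len(n) - 1) * a
  }
  ## pad plate (including the distal tip strip at reduced thickness)
  xs <- grid1(-dims$pad_L, dims$shaft_R)
  ys <- grid1(-dims$pad_T, 0)
  zs <- grid1(-dims$pad_W / 2, dims$pad_W / 2)
  pad <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  tip_zone <- pad[, 1] < -dims$pad_L + dims$tip_len
  ## taper: the tip strip keeps only the bottom bead layer
  keep <- !(tip_zone & pad[, 2] > min(ys) + a / 2)
  pad <- pad[keep, , drop = FALSE]
  region <- ifelse(pad[, 1] < -dims$pad_L + dims$tip_len, "tip", "pad")

  ## shaft: cylinder of radius shaft_R around the axis u from the origin
  u <- .shaft_axis
  ts <- grid1(a / 2, dims$shaft_L)
  rad <- grid1(-dims$shaft_R, dims$shaft_R)
  g <- as.matrix(expand.grid(t = ts, p = rad, q = rad))
  g <- g[g[, 2]^2 + g[, 3]^2 <= dims$shaft_R^2, , drop = FALSE]
  ## orthonormal frame (u, e1, e2)
  e1 <- c(1, -1, 0) / sqrt(2); e2 <- c(0, 0, 1)
  shaft <- g[, 1] %o% u + g[, 2] %o% e1 + g[, 3] %o% e2
  pos <- rbind(pad, shaft)
  region <- c(region, rep("shaft", nrow(shaft)))

  n <- nrow(pos)
  if (n < n_neighbours + 1L)
    stop("spacing too large: only ", n, " beads for ", n_neighbours,
         "-neighbour bonding", call. = FALSE)
  pos <- pos + matrix(runif(3 * n, -jitter * a, jitter * a), ncol = 3)

  bonds <- .bond_table(pos, u, k, k_b, n_neighbours)
  b0 <- bonds$b0

  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  if (min(deg) < n_neighbours)
    stop("spacing too large to achieve ", n_neighbours,
         " neighbours; minimum degree achieved: ", min(deg), call. = FALSE)

  volume <- dims$pad_L * dims$pad_W * dims$pad_T +
    pi * dims$shaft_R^2 * dims$shaft_L
  structure(list(
    pos = unname(pos),
    region = factor(region, levels = c("tip", "pad", "shaft")),
    bonds = bonds,
    fibril = u, mass = mass, k = k, k_b = k_b,
    dims = dims, spacing = spacing, jitter = jitter, seed = seed,
    volume = volume,
    bond_length_mean = mean(b0), bond_length_sd = sd(b0),
    bond_length_min = min(b0)),
    class = "spatula_model")
}

#' @export
print.spatula_model <- function(x, ...) {
  cat("<spatula_model>\n")
  cat(sprintf("  %d beads (%s), %d bonds\n", nrow(x$pos),
              paste(sprintf("%s %d", levels(x$region), table(x$region)),
                    collapse = ", "), nrow(x$bonds)))
  cat(sprintf("  bond length %.2f +/- %.2f nm (min %.2f); k = %.3g, k_b = %.3g nN/nm\n",
              x$bond_length_mean, x$bond_length_sd, x$bond_length_min,
              x$k, x$k_b))
  invisible(x)
}

## symmetrised k-nearest-neighbour bond list; ties broken by bead index.
## Chunked to keep memory bounded for large bead counts.
.knn_bonds <- function(pos, k) {
  n <- nrow(pos)
  chunk <- max(1L, floor(2e6 / n))
  pairs <- vector("list", ceiling(n / chunk))
  sq <- rowSums(pos^2)
  ci <- 0L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(sq[idx], sq, "+") - 2 * pos[idx, , drop = FALSE] %*% t(pos)
    nb <- .knn_chunk(d2, idx, k)
    ci <- ci + 1L
    pairs[[ci]] <- cbind(rep(idx, each = k), as.vector(t(nb)))
  }
  pr <- do.call(rbind, pairs)
  pr <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  unique(pr)
}

## 30-nearest-neighbour bond table with anisotropic stiffness; stores the
## |cos| against the fibril direction so constants can be re-assigned
## without rebuilding the geometry.
.bond_table <- function(pos, fibril, k_nN, kb_nN, n_neighbours) {
  bonds <- .knn_bonds(pos, n_neighbours)
  dvec <- pos[bonds[, 2], , drop = FALSE] - pos[bonds[, 1], , drop = FALSE]
  b0 <- sqrt(rowSums(dvec^2))
  cosang <- as.numeric(abs(dvec %*% fibril)) / b0
  tibble::tibble(
    i = bonds[, 1], j = bonds[, 2], b0 = b0, cos_fibril = cosang,
    K = (k_nN + kb_nN * cosang) * .nN_per_nm_to_md)
}

.knn_chunk <- function(d2, idx, k) {
  n <- ncol(d2)
  nb <- matrix(0L, length(idx), k)
  for (r in seq_along(idx)) {
    d <- d2[r, ]
    d[idx[r]] <- Inf  # exclude self
    nb[r, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  nb
}

#' Build the frozen two-layer substrate
#'
#' A lattice-like monolayer of beads forming a smooth, cavity-free surface
#' on the plane y = 0, optionally underlaid by an amorphous bulk. All
#' substrate beads are immobile; beads deeper than the non-bonded cutoff
#' cannot influence the spatula forces, so the bulk is off by default.
#'
#' @param spacing monolayer lattice spacing, nm; must be below the LJ sigma
#'   so the surface is cavity-free.
#' @param extent_x,extent_z length-2 numeric ranges (nm) the substrate must
#'   cover (typically the spatula footprint plus the interaction cutoff).
#' @param sigma LJ length parameter used for the cavity-free check, nm.
#' @param bulk logical: add the amorphous bulk?
#' @param bulk_thickness bulk slab thickness, nm.
#' @param bulk_density bulk bead number density, nm^-3; default matches one
#'   bead per monolayer cell cube.
#' @param seed seed for the amorphous bulk positions.
#' @return object of class `substrate`: list with `pos` (m x 3 matrix, nm;
#'   monolayer at y = 0, bulk below), `spacing`, `bulk`.
#' @export
build_substrate <- function(spacing = 3, extent_x, extent_z, sigma = 4,
                            bulk = FALSE, bulk_thickness = 13,
                            bulk_density = NULL, seed = 1L) {
  stopifnot(length(extent_x) == 2, length(extent_z) == 2,
            diff(extent_x) > 0, diff(extent_z) > 0)
  if (spacing >= sigma)
    stop("substrate spacing ", spacing, " nm is not cavity-free (>= sigma = ",
         sigma, " nm)", call. = FALSE)
  xs <- seq(extent_x[1], extent_x[2], by = spacing)
  zs <- seq(extent_z[1], extent_z[2], by = spacing)
  mono <- cbind(rep(xs, times = length(zs)), 0, rep(zs, each = length(xs)))
  pos <- mono
  ## regular-lattice descriptor enables the fast planar neighbour search
  lattice <- c(xs[1], zs[1], spacing, length(xs), length(zs))
  if (bulk) {
    if (is.null(bulk_density)) bulk_density <- 1 / spacing^3
    vol <- diff(extent_x) * diff(extent_z) * bulk_thickness
    nb <- round(bulk_density * vol)
    rng <- .seeded_rng(seed); on.exit(rng$restore())
    bulk_pos <- cbind(runif(nb, extent_x[1], extent_x[2]),
                      runif(nb, -bulk_thickness - spacing / 2, -spacing / 2),
                      runif(nb, extent_z[1], extent_z[2]))
    pos <- rbind(mono, bulk_pos)
  }
  structure(list(pos = unname(pos), spacing = spacing, bulk = bulk,
                 lattice = if (bulk) numeric(0) else lattice,
                 extent_x = extent_x, extent_z = extent_z),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("<substrate> %d beads (spacing %.2g nm, bulk %s)\n",
              nrow(x$pos), x$spacing, if (x$bulk) "on" else "off"))
  invisible(x)
}

## rotation matrix: rotate by angle about (unit) axis
.rot_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c_ * diag(3) + s_ * ux + (1 - c_) * (u %o% u)
}

## minimal rotation mapping unit vector a onto unit vector b
.rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- p - sum(p * a) * a
    return(.rot_axis_angle(perp, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Place a spatula model in the global frame
#'
#' Rigidly rotates and translates a spatula so its shaft axis aligns with a
#' seta branch axis, with a roll about the shaft axis selecting the contact
#' orientation: `"pad_parallel"` keeps the pad plate facing the substrate
#' (pad-dominant contact), `"tip_first"` rolls the spatula 90 degrees so
#' only the distal tip strip approaches the substrate first (tip-dominant
#' contact).
#'
#' @param model a [build_spatula()] result (local frame).
#' @param branch_axis length-3 unit vector of the final branch, pointing
#'   down (from the branching point toward the tip).
#' @param shaft_top_target global coordinates (nm) where the centre of the
#'   shaft's top cross-section should land.
#' @param orientation `"pad_parallel"` or `"tip_first"`.
#' @return the model with global `pos`, rotated `fibril`, and an
#'   `orientation` tag.
#' @export
place_spatula <- function(model, branch_axis, shaft_top_target,
                          orientation = c("pad_parallel", "tip_first")) {
  orientation <- match.arg(orientation)
  u <- model$fibril
  roll <- if (orientation == "tip_first")
    .rot_axis_angle(u, -pi / 2) else diag(3)
  b_up <- -branch_axis / sqrt(sum(branch_axis^2))
  align <- .rot_between(u, b_up)
  R <- align %*% roll
  shaft_top_local <- model$dims$shaft_L * u
  pos <- model$pos %*% t(R)
  shift <- shaft_top_target - as.numeric(R %*% shaft_top_local)
  pos <- sweep(pos, 2, shift, "+")
  model$pos <- pos
  model$fibril <- as.numeric(align %*% u)  # roll about u leaves u fixed
  model$orientation <- orientation
  model
}

#' Export a spatula (and optionally a substrate) as extended XYZ
#'
#' Writes bead coordinates with region labels; bonds go to a separate CSV
#' (`i`, `j`, `b0`, `K`).
#'
#' @param model a [build_spatula()] result.
#' @param path output `.xyz` path.
#' @param bonds_path optional output CSV path for the bond list.
#' @return `path`, invisibly.
#' @export
write_spatula_xyz <- function(model, path, bonds_path = NULL) {
  n <- nrow(model$pos)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(n),
               'Properties=species:S:1:pos:R:3:region:S:1'), con)
  writeLines(sprintf("CG %.6f %.6f %.6f %s", model$pos[, 1], model$pos[, 2],
                     model$pos[, 3], as.character(model$region)), con)
  if (!is.null(bonds_path)) {
    write.csv(model$bonds, bonds_path, row.names = FALSE)
  }
  invisible(path)
}
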