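## R surface of the molecular dynamics engine. Positions in nm, velocities
## in nm/ps, forces in kJ/mol/nm, masses in Da, time step in ps.

#' Molecular dynamics parameters
#'
#' Parameters of one MD phase. Defaults are the production values: 20 fs
#' time step, 300 K, spatula-substrate LJ with epsilon 290 kJ/mol, sigma
#' 4 nm, cutoff 12 nm (= 3 sigma, retaining most of the attractive tail),
#' stochastic velocity rescaling (tau 2 ps) outside the bridging domain and
#' Berendsen (tau 10 ps) inside, 7000 steps per iteration with forces
#' averaged over the final half (70 ps).
#'
#' @param dt_fs MD time step, fs.
#' @param T_K thermostat temperature, K.
#' @param lj_eps LJ well depth, kJ/mol.
#' @param lj_sigma LJ length parameter, nm.
#' @param r_cutoff non-bonded interaction cutoff, nm.
#' @param tau_out_ps velocity-rescaling coupling time outside the bridging
#'   domain, ps (0 disables the thermostat).
#' @param tau_in_ps Berendsen coupling time inside the bridging domain, ps
#'   (0 disables).
#' @param n_md MD steps per FEM-MD iteration.
#' @param window_frac fraction of the trajectory (from the end) over which
#'   anchor-point and substrate forces are averaged, in (0, 1].
#' @return object of class `md_params`.
#' @export
md_params <- function(dt_fs = 20, T_K = 300, lj_eps = 290, lj_sigma = 4,
                      r_cutoff = 12, tau_out_ps = 2, tau_in_ps = 10,
                      n_md = 7000, window_frac = 0.5) {
  stopifnot(dt_fs > 0, T_K >= 0, lj_eps >= 0, lj_sigma > 0, r_cutoff > 0,
            tau_out_ps >= 0, tau_in_ps >= 0, n_md >= 1,
            window_frac > 0, window_frac <= 1)
  structure(list(dt = dt_fs * 1e-3, T = T_K, lj_eps = lj_eps,
                 lj_sigma = lj_sigma, r_cutoff = r_cutoff,
                 tau_out = tau_out_ps, tau_in = tau_in_ps,
                 n_md = as.integer(n_md), window_frac = window_frac),
            class = "md_params")
}

#' @export
print.md_params <- function(x, ...) {
  cat(sprintf("<md_params> dt %.0f fs, T %g K, LJ(eps %g kJ/mol, sigma %g nm, rc %g nm)\n",
              x$dt * 1e3, x$T, x$lj_eps, x$lj_sigma, x$r_cutoff))
  cat(sprintf("  n_md %d (%.0f ps), force window %.0f%%, tau out/in %g/%g ps\n",
              x$n_md, x$n_md * x$dt, 100 * x$window_frac, x$tau_out, x$tau_in))
  invisible(x)
}

.empty_sub <- matrix(numeric(0), 0, 3)

.sub_lattice <- function(substrate) {
  if (is.null(substrate) || is.null(substrate$lattice)) numeric(0)
  else substrate$lattice
}

.ap_args <- function(aps) {
  if (is.null(aps) || length(aps$bead) == 0)
    list(bead = integer(0), pos = .empty_sub, b0 = numeric(0), k = 0)
  else
    list(bead = as.integer(aps$bead), pos = aps$pos, b0 = aps$b0,
         k = aps$k_nN_per_nm * .nN_per_nm_to_md)
}

#' Potential energy and forces of a configuration
#'
#' Evaluates the total potential energy (harmonic bonds + truncated LJ
#' against the substrate + anchor-point springs + optional constant
#' external forces) and its exact negative gradient. Pairwise forces obey
#' Newton's third law; the LJ interaction is truncated (unshifted) at the
#' cutoff.
#'
#' @param pos n x 3 bead positions, nm.
#' @param bonds tibble/data.frame with columns `i`, `j`, `b0`, `K`
#'   (stiffness in kJ/mol/nm^2), or `NULL`.
#' @param substrate a [build_substrate()] object or `NULL`.
#' @param params an [md_params()] object.
#' @param aps anchor-point set: list with `bead` (bead index per AP), `pos`
#'   (AP coordinates), `b0` (spring equilibrium lengths, nm), and
#'   `k_nN_per_nm` (spring constant); or `NULL`.
#' @param spat_id integer spatula id per bead (for per-spatula substrate
#'   force bookkeeping); default all 1.
#' @param n_spat number of spatulae.
#' @param ext_force optional n x 3 constant external force, kJ/mol/nm.
#' @return list with `energy` (kJ/mol), `forces` (n x 3, kJ/mol/nm),
#'   `ap_forces` (forces exerted by the MD system on each AP), and
#'   `sub_forces` (n_spat x 3 substrate force on each spatula).
#' @export
md_energy_forces <- function(pos, bonds = NULL, substrate = NULL,
                             params = md_params(), aps = NULL,
                             spat_id = NULL, n_spat = 1L,
                             ext_force = NULL) {
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                          b0 = numeric(0), K = numeric(0))
  sub <- if (is.null(substrate)) .empty_sub else substrate$pos
  lat <- .sub_lattice(substrate)
  ap <- .ap_args(aps)
  if (is.null(spat_id)) spat_id <- rep(1L, nrow(pos))
  .md_energy_forces_cpp(pos, as.integer(bonds$i), as.integer(bonds$j),
                        bonds$b0, bonds$K, sub, params$lj_eps,
                        params$lj_sigma, params$r_cutoff,
                        ap$bead, ap$pos, ap$b0, ap$k,
                        as.integer(spat_id), as.integer(n_spat), ext_force,
                        lat)
}

#' Maxwell-Boltzmann initial velocities
#'
#' @param n number of beads.
#' @param mass bead mass(es), Da.
#' @param T_K temperature, K.
#' @param seed integer seed.
#' @return n x 3 matrix of velocities, nm/ps.
#' @export
init_velocities <- function(n, mass, T_K = 300, seed = 1L) {
  rng <- .seeded_rng(seed); on.exit(rng$restore())
  s <- sqrt(ss_constants$k_B * T_K / rep_len(mass, n))
  matrix(rnorm(3 * n, 0, rep(s, 3)), ncol = 3)
}

#' Run one MD phase
#'
#' Advances the bead system `n_steps` velocity-Verlet steps under NVT with
#' region-dependent thermostats (stochastic velocity rescaling outside the
#' bridging domain, Berendsen inside), holding anchor points and substrate
#' fixed, and time-averages the anchor-point spring forces and the
#' substrate reaction on each spatula over the final averaging window.
#'
#' @inheritParams md_energy_forces
#' @param vel n x 3 velocities, nm/ps.
#' @param mass bead mass(es), Da.
#' @param group integer per bead: 1 = inside the bridging domain
#'   (Berendsen), 0 = outside (velocity rescaling).
#' @param n_steps number of steps; default `params$n_md`.
#' @param seed integer seed for the thermostat noise.
#' @return list with final `pos`, `vel`, `fap_avg` (time-averaged force on
#'   each AP, kJ/mol/nm), `fsub_avg` (time-averaged substrate force per
#'   spatula), `T_out`/`T_in` (mean group temperatures, K), `n_window`.
#' @export
run_md_phase <- function(pos, vel, mass, bonds, substrate = NULL,
                         params = md_params(), aps = NULL, group = NULL,
                         spat_id = NULL, n_spat = 1L, n_steps = NULL,
                         seed = 1L, ext_force = NULL) {
  n <- nrow(pos)
  if (is.null(group)) group <- rep(0L, n)
  if (is.null(spat_id)) spat_id <- rep(1L, n)
  if (is.null(n_steps)) n_steps <- params$n_md
  sub <- if (is.null(substrate)) .empty_sub else substrate$pos
  lat <- .sub_lattice(substrate)
  ap <- .ap_args(aps)
  .md_run_phase_cpp(pos, vel, rep_len(as.numeric(mass), n),
                    as.integer(bonds$i), as.integer(bonds$j),
                    bonds$b0, bonds$K,
                    sub, params$lj_eps, params$lj_sigma, params$r_cutoff,
                    ap$bead, ap$pos, ap$b0, ap$k,
                    as.integer(group), as.integer(spat_id),
                    as.integer(n_spat),
                    params$dt, as.integer(n_steps), params$T,
                    params$tau_out, params$tau_in, ss_constants$k_B,
                    params$window_frac, as.numeric(seed), ext_force, lat)
}

#' Count spatula-substrate contact points
#'
#' A contact point is a (spatula bead, substrate bead) pair closer than the
#' cutoff (strictly).
#'
#' @param pos n x 3 spatula bead positions, nm.
#' @param spat_id integer spatula id per bead.
#' @param n_spat number of spatulae.
#' @param substrate a [build_substrate()] object.
#' @param cutoff contact distance, nm (default the non-bonded cutoff 12).
#' @return integer vector of contact counts per spatula.
#' @export
count_contacts <- function(pos, spat_id = NULL, n_spat = 1L, substrate,
                           cutoff = 12) {
  stopifnot(cutoff > 0)
  if (is.null(spat_id)) spat_id <- rep(1L, nrow(pos))
  as.integer(.count_contacts_cpp(pos, as.integer(spat_id),
                                 as.integer(n_spat), substrate$pos, cutoff,
                                 .sub_lattice(substrate)))
}

## connected components of a tet mesh (used by the mesher)
cc_label_tets <- function(n_nodes, tets) {
  .cc_label_tets_cpp(as.integer(n_nodes), tets)
}

#' Check MD time-step stability
#'
#' Warns when the time step is not small against the fastest bond
#' oscillation period estimated from the stiffest bond and the neighbour
#' count.
#'
#' @param model a [build_spatula()] result.
#' @param params an [md_params()] object.
#' @return invisibly, the estimated `dt * omega_max` product.
#' @export
check_timestep <- function(model, params = md_params()) {
  k_eff <- max(model$bonds$K) * 30
  omega <- sqrt(k_eff / model$mass)
  x <- params$dt * omega
  if (x > 0.3)
    warning(sprintf(
      "time step %.0f fs is large for the stiffest bonds (dt*omega = %.2f)",
      params$dt * 1e3, x), call. = FALSE)
  invisible(x)
}
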