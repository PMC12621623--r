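## Deterministic miniature systems: a 2-level seta with 4 spatulae in
## alternating orientations, at reduced bead counts and a shortened
## protocol, so the complete build-run-analyze pipeline executes at desk
## scale. Every structural rule (parabola envelope, midpoint branching,
## 30-neighbour bonding, anchor-point pairing, thermostat split) is
## identical to the full-scale model; only sizes, counts, the
## spatula-substrate well depth, and the per-phase step counts are scaled
## down.

#' Miniature geometry parameters
#'
#' A 2-level seta (4 tips) about 1 um tall with 30 nm final branches.
#'
#' @param ... overrides passed to [geometry_params()].
#' @return a [geometry_params()] object.
#' @export
mini_geometry <- function(...) {
  args <- list(H0_um = 1.0, D0_um = 0.6, alpha_deg = 30, R_sp_nm = 30,
               eta = 2, gamma = 2, H_sp_um = 0.25, n_levels = 2,
               mesh_h_nm = 10, tip_trunc_frac = 0.3, bd_frac = 0.2)
  over <- list(...)
  args[names(over)] <- over
  do.call(geometry_params, args)
}

#' Miniature MD parameters
#'
#' Production LJ geometry (sigma 4 nm, cutoff 12 nm) with a reduced well
#' depth, shortened iterations, and a faster in-BD Berendsen coupling
#' (1 ps): with iterations of only 10 ps, the bridging domain must
#' dissipate load-step kinetic energy on a correspondingly shorter
#' timescale to keep the staggered coupling stable.
#'
#' @param ... overrides passed to [md_params()].
#' @return an [md_params()] object.
#' @export
mini_md <- function(...) {
  args <- list(dt_fs = 20, T_K = 300, lj_eps = 60, lj_sigma = 4,
               r_cutoff = 12, tau_out_ps = 2, tau_in_ps = 1,
               n_md = 500, window_frac = 0.5)
  over <- list(...)
  args[names(over)] <- over
  do.call(md_params, args)
}

#' Miniature loading protocol
#'
#' Tens of load steps: 2 nm per load step, 2 FEM-MD iterations of 500 MD
#' steps each, a preload target of about 3 nN per spatula, one relaxation
#' step.
#'
#' @param ... overrides passed to [load_protocol()].
#' @return a [load_protocol()] object.
#' @export
mini_protocol <- function(...) {
  args <- list(eps_ls_nm = 2, n_iter = 2, n_md = 500, dt_fs = 20,
               preload_nN = 12, relax_steps = 1, clearance_nm = 13,
               max_preload_steps = 120, max_pull_steps = 250)
  over <- list(...)
  args[names(over)] <- over
  do.call(load_protocol, args)
}

#' Build the miniature multiscale system
#'
#' Deterministic per seed: mini seta (2 levels, 4 spatulae: spatulae 1 and
#' 3 tip-first, 2 and 4 pad-parallel), frozen substrate, bridging domains,
#' and the shortened protocol.
#'
#' @param seed master seed.
#' @param ... overrides passed to [build_seta_system()].
#' @return a `seta_system`.
#' @export
make_mini_system <- function(seed = 1L, ...) {
  over <- list(...)
  args <- list(
    geometry = mini_geometry(),
    spatula_args = list(dims = spatula_dims("mini"), k = 0.28, k_b = 2.1,
                        mass = 1000),
    material_args = list(),
    md = mini_md(),
    protocol = mini_protocol(),
    k_ap = 1.4, k_FE = 0.08,
    substrate_spacing = 3, substrate_margin = 40,
    pad_parallel_shaft_extra = 65,
    seed = seed)
  args[names(over)] <- over
  do.call(build_seta_system, args)
}
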