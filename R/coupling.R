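## Concurrent MD-FEM coupling: bridging domains pair anchor points (virtual
## particles at bridging-domain FE nodes) with molecular beads via harmonic
## springs; the alternating iteration runs an MD phase with anchor points
## fixed, then a static FEM solve with beads frozen and the time-averaged
## anchor-point forces applied as Neumann loads, after which the updated FE
## node positions become the new anchor-point positions.

#' Loading protocol parameters
#'
#' Defines the preload-relax-pull-off schedule. Defaults are the
#' production values: 1 nm prescribed driver displacement per load step,
#' 10 FEM-MD iterations per load step, 7000 MD steps of 20 fs per
#' iteration (so one load step spans 1.4 ns and the pull-off velocity is
#' ~0.7 m/s), a 320 nN total preload target, one relaxation load step and
#' a 13 nm initial clearance (just above the 12 nm interaction cutoff).
#'
#' @param eps_ls_nm prescribed driver displacement per load step, nm.
#' @param n_iter FEM-MD iterations per load step.
#' @param n_md MD steps per iteration.
#' @param dt_fs MD time step, fs.
#' @param preload_nN total spatula-substrate compressive force ending the
#'   preloading phase, nN (scale with spatula count and bead count for
#'   reduced models).
#' @param relax_steps number of load steps without applied displacement
#'   between preload and pull-off.
#' @param clearance_nm minimum initial spatula-substrate distance, nm.
#' @param max_preload_steps,max_pull_steps safety caps on phase length.
#' @return object of class `load_protocol`.
#' @export
load_protocol <- function(eps_ls_nm = 1, n_iter = 10, n_md = 7000,
                          dt_fs = 20, preload_nN = 320, relax_steps = 1,
                          clearance_nm = 13, max_preload_steps = 400,
                          max_pull_steps = 800) {
  stopifnot(eps_ls_nm > 0, n_iter >= 1, n_md >= 1, dt_fs > 0,
            preload_nN >= 0, relax_steps >= 0, clearance_nm > 0)
  structure(list(eps_ls = eps_ls_nm, n_iter = as.integer(n_iter),
                 n_md = as.integer(n_md), dt_fs = dt_fs,
                 preload = preload_nN, relax_steps = as.integer(relax_steps),
                 clearance = clearance_nm,
                 max_preload_steps = as.integer(max_preload_steps),
                 max_pull_steps = as.integer(max_pull_steps)),
            class = "load_protocol")
}

#' Load-step duration and pull-off velocity
#'
#' The static FEM carries no time, so physical time is assigned from the
#' MD side: `dt_ls = n_iter * n_md * dt_MD`, and the pull-off velocity is
#' the prescribed displacement per load step divided by that duration.
#'
#' @param protocol a [load_protocol()] object.
#' @return list with `dt_ls_ns` (load-step duration, ns), `dt_iter_ps`
#'   (MD time per iteration, ps) and `velocity_m_s` (pull-off velocity;
#'   1 nm/ns = 1 m/s).
#' @export
load_step_time <- function(protocol) {
  dt_ls_fs <- protocol$n_iter * protocol$n_md * protocol$dt_fs
  dt_ls_ns <- dt_ls_fs * 1e-6
  list(dt_ls_ns = dt_ls_ns,
       dt_iter_ps = protocol$n_md * protocol$dt_fs * 1e-3,
       velocity_m_s = protocol$eps_ls / dt_ls_ns)
}

#' @export
print.load_protocol <- function(x, ...) {
  lt <- load_step_time(x)
  cat(sprintf("<load_protocol> %.3g nm / load step, %d iter x %d MD steps (dt_ls = %.3g ns, v = %.3g m/s)\n",
              x$eps_ls, x$n_iter, x$n_md, lt$dt_ls_ns, lt$velocity_m_s))
  cat(sprintf("  preload target %.3g nN, %d relax step(s), clearance %.3g nm\n",
              x$preload, x$relax_steps, x$clearance))
  invisible(x)
}

#' Build a bridging domain
#'
#' Creates one anchor point at every bridging-domain FE node of a spatula's
#' final branch and greedily pairs each (in ascending FE node order, ties
#' by bead index) with its nearest not-yet-paired spatula bead within a
#' distance cap. The pairing-time AP-bead distance becomes the spring
#' equilibrium length, so the springs are initially force-free.
#'
#' @param mesh a [generate_mesh()] result.
#' @param spatula a placed [build_spatula()] model (global coordinates).
#' @param s spatula index (selects `mesh$bd[[s]]`).
#' @param k_ap MD-coupling spring constant, nN/nm.
#' @param cap_factor pairing distance cap as a multiple of the mean bond
#'   length.
#' @param min_paired_frac minimum fraction of bridging-domain nodes that
#'   must find a partner bead.
#' @return object of class `bridging_domain`: list with `node` (FE node
#'   index per AP), `bead` (bead index per AP; injective), `b0`
#'   (equilibrium lengths, nm), `k_nN_per_nm`.
#' @export
build_bridging_domain <- function(mesh, spatula, s, k_ap = 0.28,
                                  cap_factor = 2, min_paired_frac = 0.35) {
  nodes <- sort(mesh$bd[[s]])
  cap <- cap_factor * spatula$bond_length_mean
  npos <- mesh$nodes[nodes, , drop = FALSE]
  bpos <- spatula$pos
  paired_bead <- integer(0); paired_node <- integer(0); b0 <- numeric(0)
  taken <- logical(nrow(bpos))
  for (ii in seq_along(nodes)) {
    d2 <- (bpos[, 1] - npos[ii, 1])^2 + (bpos[, 2] - npos[ii, 2])^2 +
      (bpos[, 3] - npos[ii, 3])^2
    d2[taken] <- Inf
    jj <- which.min(d2)  # ties resolved to the lowest bead index
    if (d2[jj] <= cap^2) {
      taken[jj] <- TRUE
      paired_node <- c(paired_node, nodes[ii])
      paired_bead <- c(paired_bead, jj)
      b0 <- c(b0, sqrt(d2[jj]))
    }
  }
  if (length(paired_node) < min_paired_frac * length(nodes))
    stop(sprintf(
      "fewer candidate beads than anchor points within the %.3g nm cap: %d of %d bridging-domain nodes paired",
      cap, length(paired_node), length(nodes)), call. = FALSE)
  structure(list(node = paired_node, bead = paired_bead, b0 = b0,
                 k_nN_per_nm = k_ap, spatula = s, cap = cap),
            class = "bridging_domain")
}

#' @export
print.bridging_domain <- function(x, ...) {
  cat(sprintf("<bridging_domain> spatula %d: %d anchor points, spring %.3g nN/nm, b0 %.2f +/- %.2f nm\n",
              x$spatula, length(x$node), x$k_nN_per_nm, mean(x$b0),
              sd(x$b0)))
  invisible(x)
}

## derive child stream seeds (< 2^31) from a master seed
.derive_seed <- function(master, stream, index = 0L) {
  (as.numeric(master) * 7919 + stream * 104729 + index * 131) %% 2147483629
}

#' Assemble a complete multiscale seta system
#'
#' Builds the seta mesh, samples the material, assembles the FEM operator,
#' builds and places one spatula per tip in alternating orientations
#' (odd-numbered spatulae tip-first, even-numbered pad-parallel), shifts
#' the whole seta so the lowest bead honours the initial clearance, builds
#' the substrate under the spatula footprint, and pairs the bridging
#' domains.
#'
#' @param geometry a [geometry_params()] object.
#' @param spatula_args list of arguments for [build_spatula()] (a fresh
#'   seeded model is generated per spatula).
#' @param material_args list of arguments for [sample_material()]
#'   (means/sds).
#' @param md an [md_params()] object.
#' @param protocol a [load_protocol()] object.
#' @param k_ap MD-coupling (anchor-point) spring constant, nN/nm.
#' @param k_FE FE-coupling (penalty) spring constant, nN/nm.
#' @param substrate_spacing substrate monolayer lattice spacing, nm.
#' @param substrate_margin substrate extent beyond the spatula footprint,
#'   nm.
#' @param mesh_h mesh resolution override, nm.
#' @param pad_parallel_shaft_extra extra shaft length (nm) given to
#'   pad-parallel spatulae so both orientations approach the substrate at
#'   comparable heights.
#' @param berendsen_scope which beads couple to the Berendsen thermostat:
#'   `"bonded"` (only beads bonded to an anchor point, the default) or
#'   `"all"` (the whole spatula; useful for strongly damped quasi-static
#'   holds).
#' @param seed master seed; all subsidiary streams (material, per-spatula
#'   jitter, initial velocities, thermostats) derive from it.
#' @return object of class `seta_system`.
#' @export
build_seta_system <- function(geometry, spatula_args = list(),
                              material_args = list(), md = md_params(),
                              protocol = load_protocol(), k_ap = 0.28,
                              k_FE = 0.08, substrate_spacing = 3,
                              substrate_margin = 60, mesh_h = NULL,
                              pad_parallel_shaft_extra = 0,
                              berendsen_scope = c("bonded", "all"),
                              seed = 1L) {
  berendsen_scope <- match.arg(berendsen_scope)
  skeleton <- build_skeleton(geometry)
  mesh <- generate_mesh(skeleton, h = mesh_h)
  material <- do.call(sample_material,
                      c(material_args,
                        list(seed = .derive_seed(seed, 1L))))
  n_spat <- nrow(skeleton$tips)

  ## build + place spatulae
  spatulae <- vector("list", n_spat)
  for (s in seq_len(n_spat)) {
    tip <- skeleton$tips[s, ]
    sargs <- spatula_args
    ## a rolled (tip-first) spatula reaches deeper than a pad-parallel
    ## one; a longer pad-parallel shaft equalises the approach heights
    if (s %% 2 == 0 && pad_parallel_shaft_extra > 0) {
      if (is.null(sargs$dims)) sargs$dims <- spatula_dims("mini")
      sargs$dims$shaft_L <- sargs$dims$shaft_L + pad_parallel_shaft_extra
    }
    model <- do.call(build_spatula,
                     c(sargs, list(seed = .derive_seed(seed, 2L, s))))
    axis <- c(tip$axis_x, tip$axis_y, tip$axis_z)
    erow <- skeleton$edges[skeleton$edges$to == tip$point, ]
    a <- as.numeric(skeleton$points[erow$from, c("x", "y", "z")])
    b <- as.numeric(skeleton$points[erow$to, c("x", "y", "z")])
    orientation <- if (s %% 2 == 1) "tip_first" else "pad_parallel"
    t_target <- 1 - 0.5 * geometry$bd_frac
    target <- a + t_target * (b - a)
    spatulae[[s]] <- place_spatula(model, axis, target, orientation)
  }

  ## global vertical shift so the lowest bead sits at the clearance height
  min_y <- min(vapply(spatulae, function(m) min(m$pos[, 2]), numeric(1)))
  shift <- protocol$clearance - min_y
  mesh$nodes[, 2] <- mesh$nodes[, 2] + shift
  mesh$skeleton$points$y <- mesh$skeleton$points$y + shift
  for (s in seq_len(n_spat)) spatulae[[s]]$pos[, 2] <-
    spatulae[[s]]$pos[, 2] + shift
  skeleton <- mesh$skeleton

  ## substrate spanning the spatula footprint (plus sliding/cutoff margin)
  xr <- range(vapply(spatulae, function(m) range(m$pos[, 1]), numeric(2)))
  zr <- range(vapply(spatulae, function(m) range(m$pos[, 3]), numeric(2)))
  substrate <- build_substrate(
    spacing = substrate_spacing, sigma = md$lj_sigma,
    extent_x = xr + c(-1, 1) * (substrate_margin + md$r_cutoff),
    extent_z = zr + c(-1, 1) * (substrate_margin + md$r_cutoff),
    seed = .derive_seed(seed, 3L))

  bds <- vector("list", n_spat)
  for (s in seq_len(n_spat))
    bds[[s]] <- build_bridging_domain(mesh, spatulae[[s]], s, k_ap = k_ap)

  ## the FE-coupling (penalty) springs act on the nodes that host anchor
  ## points: every anchored bridging-domain node carries both couplings
  mesh_pen <- mesh
  mesh_pen$bd <- lapply(bds, `[[`, "node")
  fem <- fem_system(mesh_pen, material, k_FE = k_FE)

  ## per-spatula MD bookkeeping: thermostat groups (inside BD = beads
  ## bonded to an AP) and initial velocities
  states <- vector("list", n_spat)
  for (s in seq_len(n_spat)) {
    n <- nrow(spatulae[[s]]$pos)
    group <- integer(n)
    if (berendsen_scope == "all") group[] <- 1L else
      group[bds[[s]]$bead] <- 1L
    states[[s]] <- list(
      pos = spatulae[[s]]$pos,
      vel = init_velocities(n, spatulae[[s]]$mass, md$T,
                            seed = .derive_seed(seed, 4L, s)),
      group = group)
  }

  structure(list(geometry = geometry, skeleton = skeleton, mesh = mesh,
                 material = material, fem = fem, spatulae = spatulae,
                 bds = bds, substrate = substrate, md = md,
                 protocol = protocol, k_ap = k_ap, k_FE = k_FE,
                 seed = seed, states0 = states),
            class = "seta_system")
}

#' @export
print.seta_system <- function(x, ...) {
  cat(sprintf("<seta_system> %d spatulae (%s beads each), mesh %d nodes / %d tets\n",
              length(x$spatulae),
              paste(range(vapply(x$spatulae, function(m) nrow(m$pos), numeric(1))),
                    collapse = "-"),
              nrow(x$mesh$nodes), nrow(x$mesh$tets)))
  cat(sprintf("  anchor points per spatula: %s; k_ap %.3g, k_FE %.3g nN/nm; E %.3g GPa, nu %.3g\n",
              paste(range(vapply(x$bds, function(b) length(b$node), numeric(1))),
                    collapse = "-"),
              x$k_ap, x$k_FE, x$material$E, x$material$nu))
  invisible(x)
}

## fresh mutable run state
.init_state <- function(sys) {
  list(U = numeric(3L * nrow(sys$fem$nodes)),
       spat = lapply(sys$states0, function(s) list(pos = s$pos,
                                                   vel = s$vel)),
       iter = 0L)
}

## current anchor-point positions of spatula s (deformed FE node positions)
.ap_positions <- function(sys, state, s) {
  nodes <- sys$bds[[s]]$node
  idx <- cbind(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2, 3 * (nodes - 1) + 3)
  sys$mesh$nodes[nodes, , drop = FALSE] +
    cbind(state$U[idx[, 1]], state$U[idx[, 2]], state$U[idx[, 3]])
}

#' Run one FEM-MD iteration
#'
#' (a) Each spatula advances one MD phase with its anchor points held at
#' the current (deformed) bridging-domain FE node positions; anchor-point
#' spring forces and substrate reactions are averaged over the final
#' window. (b) With beads frozen, the FEM solves one static iteration: the
#' driver nodes receive the prescribed displacement increment (first
#' iteration of a load step) or are fully constrained (subsequent
#' iterations), and the averaged anchor-point forces enter as Neumann
#' loads on the bridging-domain nodes. (c) The updated bridging-domain
#' node positions become the anchor-point positions for the next MD phase.
#'
#' @param sys a [build_seta_system()] result.
#' @param state run state (from the internal initialiser or a previous
#'   call).
#' @param driver_disp_y prescribed driver displacement increment for this
#'   iteration, nm (0 for subsequent iterations of a load step).
#' @param seed thermostat seed for this iteration.
#' @param ext_force optional list (per spatula) of constant external
#'   per-bead force matrices, kJ/mol/nm (e.g. a static weight).
#' @return updated state; diagnostic fields `fap` (per-spatula averaged AP
#'   forces, internal units), `fsub_nN` (per-spatula substrate reaction,
#'   nN), `driver_nN` (driver constraint force), `T_out`.
#' @export
run_iteration <- function(sys, state, driver_disp_y = 0, seed = 1L,
                          ext_force = NULL) {
  n_spat <- length(sys$spatulae)
  fap <- vector("list", n_spat)
  fsub <- matrix(0, n_spat, 3)
  Tout <- numeric(n_spat)
  for (s in seq_len(n_spat)) {
    bd <- sys$bds[[s]]
    aps <- list(bead = bd$bead, pos = .ap_positions(sys, state, s),
                b0 = bd$b0, k_nN_per_nm = bd$k_nN_per_nm)
    st <- state$spat[[s]]
    r <- run_md_phase(st$pos, st$vel, sys$spatulae[[s]]$mass,
                      sys$spatulae[[s]]$bonds, sys$substrate, sys$md,
                      aps = aps, group = sys$states0[[s]]$group,
                      n_steps = sys$md$n_md,
                      seed = .derive_seed(seed, 5L, s),
                      ext_force = ext_force[[s]])
    state$spat[[s]] <- list(pos = r$pos, vel = r$vel)
    fap[[s]] <- r$fap_avg
    fsub[s, ] <- r$fsub_avg * .md_force_to_nN
    Tout[s] <- r$T_out
  }

  ## FEM phase: Neumann loads from averaged AP forces (converted to nN)
  ndof <- 3L * nrow(sys$fem$nodes)
  f_ext <- numeric(ndof)
  for (s in seq_len(n_spat)) {
    nodes <- sys$bds[[s]]$node
    fm <- fap[[s]] * .md_force_to_nN
    f_ext[3 * (nodes - 1) + 1] <- f_ext[3 * (nodes - 1) + 1] + fm[, 1]
    f_ext[3 * (nodes - 1) + 2] <- f_ext[3 * (nodes - 1) + 2] + fm[, 2]
    f_ext[3 * (nodes - 1) + 3] <- f_ext[3 * (nodes - 1) + 3] + fm[, 3]
  }
  sol <- solve_static(sys$fem, driver_disp = c(0, driver_disp_y, 0),
                      f_ext = f_ext, u_prev = state$U)
  ## divergence guard on bridging-domain increments
  bd_nodes <- unlist(lapply(sys$bds, `[[`, "node"))
  bd_dofs <- as.vector(outer(3 * (bd_nodes - 1), 1:3, "+"))
  if (max(abs(sol$du[bd_dofs])) > 10 * sys$protocol$eps_ls + 1e-9)
    stop(sprintf(
      "coupling divergence: max anchor-point displacement %.3g nm in one iteration (> 10 * eps_ls)",
      max(abs(sol$du[bd_dofs]))), call. = FALSE)

  state$U <- sol$u
  state$iter <- state$iter + 1L
  state$fap <- fap
  state$fsub_nN <- fsub
  state$driver_nN <- -sol$driver_reaction  # compression-positive convention
  state$T_out <- mean(Tout)
  state
}

## per-spatula tip/pad mean positions (global frame)
.group_positions <- function(sys, state) {
  out <- vector("list", length(sys$spatulae))
  for (s in seq_along(sys$spatulae)) {
    reg <- sys$spatulae[[s]]$region
    pos <- state$spat[[s]]$pos
    out[[s]] <- c(
      tip_x = mean(pos[reg == "tip", 1]), tip_y = mean(pos[reg == "tip", 2]),
      pad_x = mean(pos[reg == "pad", 1]), pad_y = mean(pos[reg == "pad", 2]))
  }
  out
}

#' Run the preload-relax-pull-off protocol
#'
#' Phase 1 (preload): the driver moves 1 nm (times `eps_ls`) toward the
#' substrate per load step until the summed spatula-substrate compressive
#' force reaches the preload target. Phase 2 (relax): `relax_steps` load
#' steps without applied displacement. Phase 3 (pull-off): the driver
#' moves away from the substrate until every spatula has lost all
#' substrate contacts (or the step cap). Each load step runs `n_iter`
#' FEM-MD iterations (driver displaced in the first, fully constrained in
#' the rest) and records forces at the three measurement points (substrate
#' reaction, summed anchor-point force, driver constraint force; the first
#' two window-averaged over the final MD iteration, the driver force taken
#' directly at the end of the load step), contact counts, and tip/pad
#' group positions.
#'
#' @param sys a [build_seta_system()] result.
#' @param verbose print per-load-step progress?
#' @return object of class `seta_run`: list with `seta` (per-load-step
#'   tibble: step, phase, time_ns, forces), `spatula` (long tibble: step x
#'   spatula contact counts, forces, tip/pad positions), `protocol`,
#'   `dt_ls_ns`, `seed`, and the final `state`.
#' @export
run_protocol <- function(sys, verbose = FALSE) {
  pr <- sys$protocol
  lt <- load_step_time(pr)
  state <- .init_state(sys)
  n_spat <- length(sys$spatulae)

  seta_rows <- list(); spat_rows <- list()
  step <- 0L
  record_step <- function(phase) {
    contacts <- vapply(seq_len(n_spat), function(s)
      count_contacts(state$spat[[s]]$pos, substrate = sys$substrate,
                     cutoff = sys$md$r_cutoff), integer(1))
    gp <- .group_positions(sys, state)
    fap_y <- sum(vapply(state$fap, function(f) sum(f[, 2]), numeric(1))) *
      .md_force_to_nN
    seta_rows[[length(seta_rows) + 1L]] <<- tibble::tibble(
      step = step, phase = phase, time_ns = step * lt$dt_ls_ns,
      f_sub_x = sum(state$fsub_nN[, 1]), f_sub = sum(state$fsub_nN[, 2]),
      f_ap = fap_y, f_driver = state$driver_nN[2],
      contacts = sum(contacts))
    spat_rows[[length(spat_rows) + 1L]] <<- tibble::tibble(
      step = step, phase = phase, time_ns = step * lt$dt_ls_ns,
      spatula = seq_len(n_spat),
      orientation = vapply(sys$spatulae, `[[`, "", "orientation"),
      f_sub = state$fsub_nN[, 2], f_sub_x = state$fsub_nN[, 1],
      contacts = contacts,
      tip_x = vapply(gp, `[[`, 0, "tip_x"),
      tip_y = vapply(gp, `[[`, 0, "tip_y"),
      pad_x = vapply(gp, `[[`, 0, "pad_x"),
      pad_y = vapply(gp, `[[`, 0, "pad_y"))
    if (verbose)
      message(sprintf("step %4d [%8s] F_sub %8.2f nN, F_drv %8.2f nN, contacts %d",
                      step, phase, sum(state$fsub_nN[, 2]),
                      state$driver_nN[2], sum(contacts)))
  }

  do_load_step <- function(disp) {
    step <<- step + 1L
    for (it in seq_len(pr$n_iter)) {
      state <<- run_iteration(sys, state,
                              driver_disp_y = if (it == 1L) disp else 0,
                              seed = .derive_seed(sys$seed, 6L,
                                                  step * 1000L + it))
    }
  }

  ## phase 1: preload (driver moves toward the substrate) until the force
  ## target is reached and every spatula is genuinely pressed on (in
  ## contact and carrying at least a quarter of its fair share)
  phase_end <- c(preload = NA_integer_, relax = NA_integer_)
  per_spat_min <- 0.25 * pr$preload / n_spat
  repeat {
    do_load_step(-pr$eps_ls)
    record_step("preload")
    last_sp <- spat_rows[[length(spat_rows)]]
    done <- if (pr$preload <= 0) {
      ## degenerate threshold: relax begins at the first contact
      sum(last_sp$contacts) > 0
    } else {
      sum(state$fsub_nN[, 2]) >= pr$preload &&
        all(last_sp$contacts > 0) &&
        all(state$fsub_nN[, 2] >= per_spat_min)
    }
    if (done) break
    if (step >= pr$max_preload_steps)
      stop("preload target not reached in ", step, " load steps (force ",
           sprintf("%.3g", sum(state$fsub_nN[, 2])), " nN)", call. = FALSE)
  }
  phase_end["preload"] <- step

  ## phase 2: relaxation (no applied displacement)
  for (k in seq_len(pr$relax_steps)) {
    do_load_step(0)
    record_step("relax")
  }
  phase_end["relax"] <- step

  ## phase 3: pull-off (driver moves away) until full detachment
  pull_steps <- 0L
  repeat {
    do_load_step(+pr$eps_ls)
    record_step("pulloff")
    pull_steps <- pull_steps + 1L
    total_contacts <- seta_rows[[length(seta_rows)]]$contacts
    if (total_contacts == 0L || pull_steps >= pr$max_pull_steps) break
  }

  structure(list(seta = dplyr::bind_rows(seta_rows),
                 spatula = dplyr::bind_rows(spat_rows),
                 protocol = pr, dt_ls_ns = lt$dt_ls_ns,
                 phase_end = phase_end, seed = sys$seed,
                 n_spat = n_spat, state = state),
            class = "seta_run")
}

#' @export
print.seta_run <- function(x, ...) {
  cat(sprintf("<seta_run> %d load steps (%.3g ns), %d spatulae\n",
              max(x$seta$step), max(x$seta$time_ns), x$n_spat))
  cat(sprintf("  preload ends at step %d; peak compression %.3g nN; peak adhesion %.3g nN\n",
              x$phase_end["preload"], max(x$seta$f_sub), min(x$seta$f_sub)))
  invisible(x)
}

#' Constant-velocity shear protocol (pure MD)
#'
#' Supplementary friction measurement on a single pad-parallel
#' spatula-substrate system without the FE seta: anchor points are created
#' on the shaft beads, displaced toward the substrate until the target
#' preload is reached, then dragged along +X at constant velocity while Y
#' and Z are held. Lateral and normal substrate forces are window-averaged
#' per chunk; the apparent friction coefficient is their ratio over the
#' steady sliding window.
#'
#' @param spatula a [build_spatula()] model (used in its local frame,
#'   rolled pad-parallel onto the substrate).
#' @param substrate a [build_substrate()] object (must span the sliding
#'   distance).
#' @param speed_m_s shear speed, m/s (= nm/ns).
#' @param preload_nN target normal preload, nN.
#' @param distance_nm total sliding distance, nm.
#' @param md an [md_params()] object; chunk length = `n_md` steps.
#' @param k_ap anchor spring constant, nN/nm.
#' @param clearance_nm initial height of the lowest bead, nm.
#' @param seed integer seed.
#' @return tibble per chunk: time_ns, ap_x (imposed AP displacement),
#'   f_lat, f_norm (nN), phase.
#' @export
run_shear_protocol <- function(spatula, substrate, speed_m_s = 1,
                               preload_nN = 5, distance_nm = 20,
                               md = md_params(), k_ap = 0.28,
                               clearance_nm = 13, seed = 1L) {
  pos <- spatula$pos
  pos[, 2] <- pos[, 2] - min(pos[, 2]) + clearance_nm
  n <- nrow(pos)
  shaft <- which(spatula$region == "shaft")
  aps <- list(bead = shaft, pos = pos[shaft, , drop = FALSE],
              b0 = rep(0, length(shaft)), k_nN_per_nm = k_ap)
  group <- integer(n); group[shaft] <- 1L
  vel <- init_velocities(n, spatula$mass, md$T,
                         seed = .derive_seed(seed, 7L))
  dt_chunk_ns <- md$n_md * (md$dt * 1e-3)  # ps -> ns
  rows <- list(); t_ns <- 0; k <- 0L

  run_chunk <- function(phase) {
    k <<- k + 1L
    r <- run_md_phase(pos, vel, spatula$mass, spatula$bonds, substrate,
                      md, aps = aps, group = group,
                      seed = .derive_seed(seed, 8L, k))
    pos <<- r$pos; vel <<- r$vel
    t_ns <<- t_ns + dt_chunk_ns
    f <- r$fsub_avg[1, ] * .md_force_to_nN
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      time_ns = t_ns, phase = phase, ap_x = mean(aps$pos[, 1]),
      ap_y = mean(aps$pos[, 2]), f_lat = f[1], f_norm = f[2])
    f
  }

  ## preload: lower the APs 1 nm per chunk until the normal force target
  for (i in 1:200) {
    aps$pos[, 2] <- aps$pos[, 2] - 1
    f <- run_chunk("preload")
    if (f[2] >= preload_nN) break
  }
  if (rows[[length(rows)]]$f_norm < preload_nN)
    warning("shear preload target not reached", call. = FALSE)
  ## short hold
  for (i in 1:2) run_chunk("hold")
  ## shear at constant velocity: displace APs per chunk
  dx <- speed_m_s * dt_chunk_ns  # nm per chunk
  n_chunks <- max(3L, ceiling(distance_nm / dx))
  for (i in seq_len(n_chunks)) {
    aps$pos[, 1] <- aps$pos[, 1] + dx
    run_chunk("shear")
  }
  out <- dplyr::bind_rows(rows)
  out$speed_m_s <- speed_m_s
  out
}
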