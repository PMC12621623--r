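test_that("load-step timing follows the MD-side clock", {
  pr <- load_protocol()  # production defaults
  lt <- load_step_time(pr)
  expect_equal(lt$dt_ls_ns, 1.4)                 # 10 x 7000 x 20 fs
  expect_equal(lt$dt_iter_ps, 140)               # MD time per iteration
  expect_equal(round(lt$velocity_m_s, 1), 0.7)   # 1 nm per 1.4 ns
  expect_equal(lt$velocity_m_s, 1 / 1.4, tolerance = 1e-12)
  pr1 <- load_protocol(n_iter = 1)
  expect_equal(load_step_time(pr1)$dt_ls_ns, 0.14)  # linear in n_iter
})

test_that("anchor-point pairing is injective, greedy and capped", {
  ## beads exactly at the node positions pair with zero-length springs
  set.seed(41)
  nodes <- matrix(runif(30, 0, 50), 10, 3)
  mesh <- list(nodes = nodes, bd = list(seq_len(10)))
  sp <- list(pos = nodes, bond_length_mean = 8)
  bd <- build_bridging_domain(mesh, sp, 1)
  expect_equal(bd$b0, rep(0, 10))
  expect_identical(sort(bd$bead), 1:10)

  ## random 10 AP / 20 bead instance: matches an independently coded
  ## greedy matcher with the same node-order/tie-break rule
  beads <- matrix(runif(60, 0, 50), 20, 3)
  sp2 <- list(pos = beads, bond_length_mean = 30)
  bd2 <- build_bridging_domain(mesh, sp2, 1, cap_factor = 2)
  taken <- logical(20); oracle <- integer(0)
  for (ii in 1:10) {
    d <- sqrt(colSums((t(beads) - nodes[ii, ])^2))
    d[taken] <- Inf
    j <- which.min(d)
    if (d[j] <= 60) { oracle <- c(oracle, j); taken[j] <- TRUE }
  }
  expect_identical(bd2$bead, oracle)
  expect_false(anyDuplicated(bd2$bead) > 0)

  ## cap too small: rejected with counts
  sp3 <- list(pos = beads + 100, bond_length_mean = 1)
  expect_error(build_bridging_domain(mesh, sp3, 1),
               "fewer candidate beads")
})

test_that("a coupled iteration is deterministic given seed and state", {
  sys <- get_mini_sys()
  st0 <- setascale:::.init_state(sys)
  a <- run_iteration(sys, st0, driver_disp_y = -2, seed = 77)
  b <- run_iteration(sys, st0, driver_disp_y = -2, seed = 77)
  expect_identical(a$U, b$U)
  expect_identical(a$spat[[1]]$pos, b$spat[[1]]$pos)
  expect_identical(a$fsub_nN, b$fsub_nN)
  ## a different seed changes the thermostat noise, hence the trajectory
  c_ <- run_iteration(sys, st0, driver_disp_y = -2, seed = 78)
  expect_false(identical(a$spat[[1]]$pos, c_$spat[[1]]$pos))
})

test_that("without driver motion or loads the FE mesh stays put", {
  sys <- get_mini_sys()
  sol <- solve_static(sys$fem, driver_disp = c(0, 0, 0))
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$driver_reaction, c(0, 0, 0))
})

test_that("system build is deterministic and alternates orientations", {
  s1 <- get_mini_sys()
  s2 <- make_mini_system(seed = 1)
  expect_identical(s1$spatulae[[2]]$pos, s2$spatulae[[2]]$pos)
  expect_identical(s1$mesh$nodes, s2$mesh$nodes)
  expect_identical(s1$material$E, s2$material$E)
  ors <- vapply(s1$spatulae, `[[`, "", "orientation")
  expect_identical(ors, c("tip_first", "pad_parallel",
                          "tip_first", "pad_parallel"))
  ## clearance honoured: lowest bead at 13 nm
  miny <- min(vapply(s1$spatulae, function(m) min(m$pos[, 2]), numeric(1)))
  expect_equal(miny, s1$protocol$clearance, tolerance = 1e-9)
  ## a different master seed yields different bead jitter
  s3 <- make_mini_system(seed = 2)
  expect_false(identical(s1$spatulae[[1]]$pos, s3$spatulae[[1]]$pos))
})

test_that("with no substrate interaction the protocol is elastically reversible", {
  sys <- make_mini_system(seed = 3, geometry = mini_geometry(n_levels = 1),
                          md = mini_md(lj_eps = 0, tau_out_ps = 10,
                                       n_md = 800),
                          protocol = mini_protocol(eps_ls_nm = 1, n_md = 800,
                                                   preload_nN = 0,
                                                   relax_steps = 0,
                                                   max_pull_steps = 60))
  run <- run_protocol(sys)
  ## degenerate threshold: relax/pull-off begins right after first contact
  expect_gt(run$seta$contacts[run$phase_end["preload"]], 0)
  ## substrate force identically zero throughout (no interaction)
  expect_equal(max(abs(run$seta$f_sub)), 0)
  expect_equal(max(abs(run$seta$f_sub_x)), 0)
  ## pull-off withdraws the spatulae until no geometric contacts remain
  expect_identical(utils::tail(run$seta$contacts, 1), 0L)
  ## elastic reversibility: after a short settling hold the mesh carries
  ## no residual internal deformation (near-uniform translation)
  st <- run$state
  for (i in 1:8)
    st <- run_iteration(sys, st, driver_disp_y = 0, seed = 9000 + i)
  uy <- st$U[seq(2, length(st$U), 3)]
  expect_lt(diff(range(uy)), 3)
})

test_that("shear protocol records sliding forces per chunk", {
  sp <- build_spatula(dims = spatula_dims("mini"), k = 0.28, k_b = 2.1,
                      mass = 1000, seed = 9)
  sub <- build_substrate(spacing = 3,
                         extent_x = range(sp$pos[, 1]) + c(-40, 80),
                         extent_z = range(sp$pos[, 3]) + c(-40, 40))
  out <- run_shear_protocol(sp, sub, speed_m_s = 10, preload_nN = 2,
                            distance_nm = 10, md = mini_md(), k_ap = 1.4,
                            seed = 4)
  expect_true(all(c("preload", "shear") %in% out$phase))
  sh <- out[out$phase == "shear", ]
  expect_gt(nrow(sh), 2)
  ## imposed AP displacement advances at the commanded speed
  dx <- diff(sh$ap_x)
  expect_equal(mean(dx) / diff(sh$time_ns)[1], 10, tolerance = 1e-6)
})
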