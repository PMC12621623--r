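test_that("bond and LJ forces vanish at their potential minima", {
  ## bond at its equilibrium length
  pos <- rbind(c(0, 0, 0), c(5, 0, 0))
  b <- data.frame(i = 1L, j = 2L, b0 = 5, K = 100)
  ef <- md_energy_forces(pos, b, params = md_params(lj_eps = 0))
  expect_equal(max(abs(ef$forces)), 0, tolerance = 1e-12)
  ## single LJ pair at r = 2^(1/6) sigma: zero force, energy -eps
  prm <- md_params()  # eps 290, sigma 4
  sub1 <- list(pos = matrix(c(0, 0, 0), 1, 3))
  p1 <- matrix(c(0, 2^(1 / 6) * prm$lj_sigma, 0), 1, 3)
  ef2 <- md_energy_forces(p1, substrate = sub1, params = prm)
  expect_equal(ef2$energy, -prm$lj_eps, tolerance = 1e-10)
  expect_equal(max(abs(ef2$forces)), 0, tolerance = 1e-8)
})

test_that("forces are the exact negative gradient of the energy", {
  set.seed(21)
  n <- 50
  ## sane configuration: bonded cloud hovering near (not inside) substrate
  pos <- cbind(runif(n, 0, 40), runif(n, 4, 25), runif(n, 0, 40))
  bonds <- setascale:::.bond_table(pos, c(1, 0, 0), 0.28, 0.5, 6)
  sub <- build_substrate(spacing = 3, extent_x = c(-15, 55),
                         extent_z = c(-15, 55))
  aps <- list(bead = 1:8, pos = pos[1:8, ] + 1, b0 = runif(8, 0, 2),
              k_nN_per_nm = 0.28)
  prm <- md_params()
  ef <- md_energy_forces(pos, bonds, sub, prm, aps = aps)
  h <- 5e-5
  for (tr in 1:30) {
    i <- sample(n, 1); d <- sample(3, 1)
    pp <- pos; pp[i, d] <- pp[i, d] + h
    ep <- md_energy_forces(pp, bonds, sub, prm, aps = aps)$energy
    pm_ <- pos; pm_[i, d] <- pm_[i, d] - h
    em <- md_energy_forces(pm_, bonds, sub, prm, aps = aps)$energy
    fd <- -(ep - em) / (2 * h)
    expect_lt(abs(ef$forces[i, d] - fd) / max(1, abs(fd)), 1e-6)
  }
})

test_that("internal forces balance and external forces are accounted", {
  set.seed(22)
  n <- 60
  pos <- cbind(runif(n, 0, 30), runif(n, 4, 20), runif(n, 0, 30))
  bonds <- setascale:::.bond_table(pos, c(0, 1, 0), 0.28, 0.3, 8)
  ## isolated network: total bond force sums to zero
  ef0 <- md_energy_forces(pos, bonds, params = md_params(lj_eps = 0))
  expect_equal(max(abs(colSums(ef0$forces))), 0, tolerance = 1e-9)
  ## with substrate and APs: sum(forces) = sum(substrate) - sum(on APs)
  sub <- build_substrate(spacing = 3, extent_x = c(-15, 45),
                         extent_z = c(-15, 45))
  aps <- list(bead = 1:5, pos = pos[1:5, ] + 0.7, b0 = rep(0.3, 5),
              k_nN_per_nm = 0.28)
  ef <- md_energy_forces(pos, bonds, sub, md_params(), aps = aps)
  lhs <- colSums(ef$forces)
  rhs <- colSums(ef$sub_forces) - colSums(ef$ap_forces)
  expect_equal(lhs, rhs, tolerance = 1e-9 * max(1, max(abs(lhs))))
})

test_that("velocity Verlet reproduces free flight and the harmonic period", {
  ## zero forces: uniform straight-line motion
  pos <- matrix(c(0, 0, 0), 1, 3)
  vel <- matrix(c(1, -2, 0.5), 1, 3)
  prm <- md_params(lj_eps = 0, tau_out_ps = 0, tau_in_ps = 0)
  nob <- data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                    K = numeric(0))
  r <- run_md_phase(pos, vel, 65228, nob, params = prm, n_steps = 100)
  expect_equal(r$pos[1, ], c(1, -2, 0.5) * 100 * prm$dt, tolerance = 1e-12)

  ## single bead on a harmonic spring: period 2*pi*sqrt(m/K) within 0.1%
  m <- 65228; K <- 500; b0 <- 5; A <- 1
  b <- data.frame(i = 1L, j = 2L, b0 = b0, K = K)
  pos2 <- rbind(c(0, 0, 0), c(b0 + A, 0, 0))
  vel2 <- matrix(0, 2, 3)
  Tper <- 2 * pi * sqrt(m / K)
  n10 <- round(10 * Tper / prm$dt)
  r2 <- run_md_phase(pos2, vel2, c(1e30, m), b, params = prm, n_steps = n10)
  ## after ten periods the oscillator must be back at its turning point;
  ## a relative period error p shifts the phase by 20*pi*p
  dev <- abs(r2$pos[2, 1] - (b0 + A))
  phase_err <- acos(max(-1, min(1, (r2$pos[2, 1] - b0) / A)))
  expect_lt(phase_err / (20 * pi), 1e-3)
  expect_lt(dev, A * 0.02)
})

test_that("a static stretched anchor spring transmits exactly -K(r-b0)", {
  pos <- matrix(c(0, 10, 0), 1, 3)
  aps <- list(bead = 1L, pos = matrix(c(0, 14, 0), 1, 3), b0 = 1,
              k_nN_per_nm = 0.28)
  prm <- md_params(lj_eps = 0, tau_out_ps = 0, tau_in_ps = 0,
                   window_frac = 1)
  nob <- data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                    K = numeric(0))
  ## frozen bead (effectively infinite mass), zero temperature
  r <- run_md_phase(pos, matrix(0, 1, 3), 1e30, nob, params = prm,
                    aps = aps, n_steps = 50)
  k_int <- 0.28 * setascale:::.nN_per_nm_to_md
  ## spring stretched by (4 - 1) = 3 nm along +y from bead to AP:
  ## the MD system pulls the AP toward the bead (-y)
  expect_equal(r$fap_avg[1, ], c(0, -k_int * 3, 0), tolerance = 1e-9)
})

test_that("averaging window spans half of the iteration", {
  prm <- md_params()  # n_md 7000, dt 20 fs, window 0.5
  expect_equal(prm$n_md * prm$dt * prm$window_frac, 70)  # ps
  pos <- matrix(c(0, 0, 0), 1, 3)
  nob <- data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                    K = numeric(0))
  r <- run_md_phase(pos, matrix(0, 1, 3), 65228, nob,
                    params = md_params(lj_eps = 0, tau_out_ps = 0,
                                       tau_in_ps = 0, n_md = 7000),
                    n_steps = 7000)
  expect_equal(r$n_window, 3500)
})

test_that("thermostats hold the outside-BD group near the target temperature", {
  sp <- build_spatula(seed = 31)
  n <- nrow(sp$pos)
  vel <- init_velocities(n, sp$mass, 300, seed = 32)
  prm <- md_params(lj_eps = 0)
  ## equilibrate, then measure
  r1 <- run_md_phase(sp$pos, vel, sp$mass, sp$bonds, params = prm,
                     n_steps = 8000, seed = 33)
  r2 <- run_md_phase(r1$pos, r1$vel, sp$mass, sp$bonds, params = prm,
                     n_steps = 15000, seed = 34)
  expect_lt(abs(r2$T_out - 300), 5)
})

test_that("isolated network under NVE conserves centre-of-mass velocity", {
  sp <- build_spatula(seed = 35)
  n <- nrow(sp$pos)
  vel <- init_velocities(n, sp$mass, 300, seed = 36)
  prm <- md_params(lj_eps = 0, tau_out_ps = 0, tau_in_ps = 0)
  v0 <- colMeans(vel)
  r <- run_md_phase(sp$pos, vel, sp$mass, sp$bonds, params = prm,
                    n_steps = 2000)
  expect_equal(colMeans(r$vel), v0, tolerance = 1e-10)
})

test_that("interactions beyond the cutoff carry a small tail at contact", {
  ## the unshifted LJ at r_cutoff = 3 sigma retains most of the attractive
  ## tail: doubling the cutoff shifts the substrate force at contact by a
  ## few percent only
  sp <- build_spatula(seed = 37)
  pos <- sp$pos
  pos[, 2] <- pos[, 2] - min(pos[, 2]) + 4   # resting height ~ sigma
  sub <- build_substrate(spacing = 3,
                         extent_x = range(pos[, 1]) + c(-30, 30),
                         extent_z = range(pos[, 3]) + c(-30, 30))
  f1 <- md_energy_forces(pos, sp$bonds, sub, md_params())$sub_forces
  f2 <- md_energy_forces(pos, sp$bonds, sub,
                         md_params(r_cutoff = 24))$sub_forces
  expect_lt(abs(f2[1, 2] - f1[1, 2]) / abs(f1[1, 2]), 0.05)
})

test_that("unphysical states are rejected", {
  pos <- rbind(c(0, 0, 0), c(1e-8, 0, 0))
  b <- data.frame(i = 1L, j = 2L, b0 = 1, K = 10)
  expect_error(md_energy_forces(pos, b, params = md_params(lj_eps = 0)),
               "overlapping")
})
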