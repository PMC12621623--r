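test_that("contact counting matches brute force and edge cases", {
  sub <- build_substrate(spacing = 3, extent_x = c(-30, 30),
                         extent_z = c(-30, 30))
  ## all pairs beyond the cutoff
  far <- matrix(c(0, 50, 0), 1, 3)
  expect_identical(count_contacts(far, substrate = sub, cutoff = 12), 0L)
  ## exactly one pair below the cutoff (bead 11 nm above a lattice bead)
  one <- matrix(c(0, 11, 0), 1, 3)
  sub1 <- list(pos = matrix(c(0, 0, 0), 1, 3), lattice = numeric(0))
  expect_identical(count_contacts(one, substrate = sub1, cutoff = 12), 1L)
  ## strict inequality at the boundary
  expect_identical(count_contacts(matrix(c(0, 12, 0), 1, 3),
                                  substrate = sub1, cutoff = 12), 0L)
  ## random cloud vs exhaustive double loop
  set.seed(51)
  pos <- cbind(runif(30, -25, 25), runif(30, 0, 20), runif(30, -25, 25))
  got <- count_contacts(pos, substrate = sub, cutoff = 12)
  brute <- 0L
  for (i in 1:30) for (j in seq_len(nrow(sub$pos))) {
    if (sum((pos[i, ] - sub$pos[j, ])^2) < 144) brute <- brute + 1L
  }
  expect_identical(got, brute)
})

test_that("the naive per-spatula average divides the seta minimum", {
  ## 16 identical synthetic curves with a -284.5 nN seta minimum
  n_steps <- 41; n_spat <- 16   # odd length so the curve peak is on-grid
  f_one <- -284.5 / 16 * sin(seq(0, pi, length.out = n_steps))
  f <- matrix(rep(f_one, n_spat), ncol = n_spat)
  contacts <- matrix(5L, n_steps, n_spat); contacts[n_steps, ] <- 0L
  run <- fake_run(f, contacts)
  m <- per_spatula_minima(run)
  expect_equal(m$seta_min, -284.5, tolerance = 1e-10)
  expect_equal(m$naive_average, 17.78, tolerance = 1e-3)
  expect_equal(round(m$naive_average), 18)
  ## identical curves: both conventions agree
  expect_equal(m$per_spatula_average, m$naive_average, tolerance = 1e-10)
})

test_that("staggered minima make the per-spatula average exceed the naive one", {
  ## 3-curve toy, hand-computed: minima -10, -8, -6 at different steps;
  ## seta-level minimum = min of sums = -18 at step 2 -> naive 6,
  ## per-spatula (10+8+6)/3 = 8
  f <- cbind(c(-10, -4, -2), c(-4, -8, -2), c(-2, -6, -6))
  ## row sums: -16, -18, -10
  contacts <- matrix(c(1L, 1L, 0L), 3, 3)
  run <- fake_run(f, contacts)
  m <- per_spatula_minima(run)
  expect_equal(m$seta_min, -18)
  expect_equal(m$naive_average, 6)
  expect_equal(m$per_spatula_average, 8)
  expect_gt(m$per_spatula_average, m$naive_average)
})

test_that("per-spatula average is never below naive (property)", {
  set.seed(52)
  for (rep in 1:20) {
    n_steps <- sample(10:40, 1); n_spat <- sample(2:8, 1)
    f <- matrix(-runif(n_steps * n_spat, 0, 10), n_steps, n_spat)
    contacts <- matrix(1L, n_steps, n_spat)
    m <- per_spatula_minima(fake_run(f, contacts))
    expect_gte(m$per_spatula_average + 1e-12, m$naive_average)
  }
})

test_that("detachment uses the stays-zero rule and the load-step clock", {
  ## toy series [3,1,0,1,0,0,0]: detachment at the 5th step, not the 3rd
  contacts <- matrix(c(3L, 1L, 0L, 1L, 0L, 0L, 0L), ncol = 1)
  f <- matrix(-c(1, 5, 2, 4, 1, 0.5, 0.1), ncol = 1)
  run <- fake_run(f, contacts, dt_ls_ns = 1.4)
  ev <- detect_detachment(run)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$detach_step, 5L)
  expect_equal(ev$detach_time_ns, 7)
  ## peak adhesion precedes detachment
  expect_lte(ev$peak_time_ns, ev$detach_time_ns)
  expect_equal(ev$F_min_abs, 5)
  ## the printed load-step clock: step 376 at 1.4 ns/step is ~526 ns
  expect_equal(round(376 * run$dt_ls_ns), 526)
  ## a spatula that never loses contact produces no event
  run2 <- fake_run(f, matrix(2L, 7, 1))
  expect_equal(nrow(detect_detachment(run2)), 0L)
})

test_that("sliding velocity is an OLS slope in m/s", {
  t <- seq(0, 14, by = 1.4)
  expect_equal(sliding_velocity(t, rep(3, length(t)))$velocity_m_s, 0)
  ## 1 nm per 1.4 ns ramp
  sv <- sliding_velocity(t, t / 1.4)
  expect_equal(sv$velocity_m_s, 0.714, tolerance = 1e-3)
  expect_error(sliding_velocity(t[1:2], t[1:2]), "fewer than 3")
  ## noisy ramp: slope within 2 standard errors of the truth, and the
  ## reported se matches the closed-form OLS variance
  set.seed(53)
  tt <- seq(0, 50, by = 0.5)
  y <- 0.66 * tt + rnorm(length(tt), 0, 0.2)
  sv2 <- sliding_velocity(tt, y)
  expect_lt(abs(sv2$velocity_m_s - 0.66), 2 * sv2$se)
  res <- y - (mean(y) + sv2$velocity_m_s * (tt - mean(tt)))
  se_closed <- sqrt(sum(res^2) / (length(tt) - 2) /
                      sum((tt - mean(tt))^2))
  expect_equal(sv2$se, se_closed, tolerance = 1e-6)
})

test_that("friction coefficient is a force-magnitude ratio with guards", {
  expect_equal(friction_coefficient(rep(0, 5), rep(-3, 5)), 0)
  expect_equal(friction_coefficient(rep(2, 5), rep(-10, 5)), 0.2)
  expect_error(friction_coefficient(c(1, 1), c(-1, 1)), "changes sign")
  expect_error(friction_coefficient(c(1, 1), c(0, 0)), "zero")
})

test_that("run records expose tidy/glance views", {
  f <- cbind(c(2, -3, -1, 0), c(1, -2, -4, 0))
  contacts <- rbind(c(3L, 4L), c(2L, 3L), c(1L, 1L), c(0L, 0L))
  run <- fake_run(f, contacts)
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("spatula", "f_sub", "contacts") %in% names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$peak_adhesion_nN, 5)  # |min of the summed curve|
})
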