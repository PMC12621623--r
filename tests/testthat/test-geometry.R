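test_that("guiding parabola matches the implicit envelope equation", {
  expect_equal(parabola_x(0, 10, 5), 10)                 # vertex
  expect_equal(parabola_x(7, 7, 7), 7 * sqrt(2))         # symmetry point
  ## full-scale parameters: root-find the implicit equation independently
  C1 <- 6750; C2 <- C1 * tan(30 * pi / 180); y <- 3897
  x_oracle <- uniroot(function(x) x^2 / C1^2 - y^2 / C2^2 - 1,
                      c(C1, 100 * C1), tol = 1e-10)$root
  expect_equal(parabola_x(y, C1, C2), x_oracle, tolerance = 1e-8)
  expect_error(parabola_x(1, -1, 5), "positive")
  expect_error(parabola_x(-1, 1, 5), "non-negative")
})

test_that("branching heights and widths follow the scaling laws", {
  p <- geometry_params()   # full-scale defaults
  H <- branch_heights(p)
  expect_equal(unname(H["H4"]), 670)                      # exponent zero
  expect_equal(unname(H["H3"]), 2.417 * 670, tolerance = 1e-12)
  expect_equal(unname(H["H3"]) / 1e3, 1.619, tolerance = 1e-3)
  ## recomputed total height agrees with the printed 22.8 um within 0.5%
  expect_equal(unname(H["H0"]) / 1e3, 22.8, tolerance = 0.005)
  W <- branch_widths(p)
  expect_equal(unname(W["W5"]), 50)
  expect_equal(unname(W["W0"]), 2.417^5 * 50, tolerance = 1e-12)
  expect_true(all(diff(H) < 0) && all(diff(W) < 0))       # strict monotone
  ## widths collapse to R_sp as gamma -> 1
  p2 <- geometry_params(gamma = 1 + 1e-9)
  expect_equal(max(abs(branch_widths(p2) - 50)), 0, tolerance = 1e-5)
})

test_that("skeleton branching counts and midpoint placement are exact", {
  p <- geometry_params()
  sk <- build_skeleton(p)
  lv <- table(sk$points$level)
  expect_identical(as.integer(lv[as.character(1:4)]), c(1L, 2L, 4L, 8L))
  expect_equal(nrow(sk$tips), 16L)
  p1 <- geometry_params(n_levels = 1)
  sk1 <- build_skeleton(p1)
  expect_identical(sum(sk1$points$level == 1), 1L)
  expect_equal(nrow(sk1$tips), 2L)

  ## 2-level skeleton: independent midpoint computation
  pm <- mini_geometry()
  skm <- build_skeleton(pm)
  for (i in 1:2) {
    y <- pm$eta^(pm$n_levels - i) * pm$H_sp
    lo <- pm$C1[1] * sqrt(1 + (y / pm$C2[1])^2)
    hi <- pm$C1[2] * sqrt(1 + (y / pm$C2[2])^2)
    n_int <- 2^(i - 1)
    mids <- lo + ((1:n_int) - 0.5) * (hi - lo) / n_int
    got <- sort(skm$points$x[skm$points$level == i])
    expect_equal(got, mids, tolerance = 1e-12)
  }
  ## all branching points lie between the parabolas; heights decrease
  bp <- skm$points[skm$points$level >= 1 & skm$points$level <= 2, ]
  for (r in seq_len(nrow(bp))) {
    lo <- parabola_x(bp$y[r], pm$C1[1], pm$C2[1])
    hi <- parabola_x(bp$y[r], pm$C1[2], pm$C2[2])
    expect_true(bp$x[r] > lo && bp$x[r] < hi)
  }
  h_by_level <- tapply(skm$points$y, skm$points$level, unique)
  expect_true(all(diff(unlist(h_by_level)) < 0))
})

test_that("mesh generation is sane, deterministic and translation invariant", {
  pm <- mini_geometry()
  skm <- build_skeleton(pm)
  msh <- generate_mesh(skm)

  v <- setascale:::.tet_volumes(msh$nodes, msh$tets)
  expect_gt(min(v), 0)
  ## single connected component
  comp <- setascale:::cc_label_tets(nrow(msh$nodes), msh$tets)
  expect_equal(length(unique(comp$node_comp)), 1L)
  ## driver nodes on the truncation plane (shifted mesh: plane = max y)
  expect_true(all(abs(msh$nodes[msh$driver, 2] - pm$H0) < 1e-6))
  ## bridging domains disjoint from each other and the driver set
  all_bd <- unlist(msh$bd)
  expect_false(anyDuplicated(all_bd) > 0)
  expect_length(intersect(all_bd, msh$driver), 0)
  ## boundary surface of the voxel solid is a single closed shell
  expect_equal(setascale:::mesh_boundary_euler(msh), 2L)

  ## bit-for-bit reproducibility
  msh2 <- generate_mesh(build_skeleton(pm))
  expect_identical(msh$nodes, msh2$nodes)
  expect_identical(msh$tets, msh2$tets)

  ## rigid translation: same connectivity and node sets
  skt <- skm
  dx <- 1024; dy <- 512
  skt$points$x <- skt$points$x + dx; skt$points$y <- skt$points$y + dy
  skt$tips$x_cut <- skt$tips$x_cut + dx; skt$tips$y_cut <- skt$tips$y_cut + dy
  skt$params$H0 <- skt$params$H0 + dy
  msht <- generate_mesh(skt)
  expect_identical(msh$tets, msht$tets)
  expect_identical(msh$driver, msht$driver)
  expect_identical(msh$bd, msht$bd)
  expect_equal(sweep(msht$nodes, 2, c(dx, dy, 0)), msh$nodes,
               tolerance = 1e-9)
})

test_that("mesh volume approximates the union-of-frusta solid", {
  pm <- mini_geometry()
  skm <- build_skeleton(pm)
  msh <- generate_mesh(skm)
  ## independent dense-quadrature estimate of the solid volume
  v_solid <- setascale:::skeleton_solid_volume(skm, hq = msh$h / 3)
  expect_equal(mesh_volume(msh), v_solid, tolerance = 0.05)
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(geometry_params(eta = 0.9), "eta")
  expect_error(geometry_params(gamma = 1), "gamma")
  expect_error(geometry_params(alpha_deg = 95), "alpha")
})
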