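## independent element-stiffness oracle: coordinate-matrix inversion form
## of the constant-strain tetrahedron
.oracle_tet_K <- function(X, lambda, mu) {
  M <- cbind(1, X)              # 4 x 4, rows (1, x, y, z)
  C <- solve(M)                 # shape funcs N_a = C[1,a] + C[2:4,a].x
  V <- abs(det(M)) / 6
  g <- t(C[2:4, ])              # dN_a/dx_d
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[a, 1]; B[2, c0 + 2] <- g[a, 2]; B[3, c0 + 3] <- g[a, 3]
    B[4, c0 + 1] <- g[a, 2]; B[4, c0 + 2] <- g[a, 1]
    B[5, c0 + 2] <- g[a, 3]; B[5, c0 + 3] <- g[a, 2]
    B[6, c0 + 1] <- g[a, 3]; B[6, c0 + 3] <- g[a, 1]
  }
  V * t(B) %*% D %*% B
}

test_that("element stiffness matches an independently assembled matrix", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(2 / 3)))   # regular tetrahedron
  mat <- elastic_params(4.518, 0.401)
  tr <- setascale:::.fem_assemble_p1_cpp(X, matrix(1:4, 1, 4),
                                         mat$lambda, mat$mu)
  Kc <- as.matrix(Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$v,
                                       dims = c(12, 12)))
  Ko <- .oracle_tet_K(X, mat$lambda, mat$mu)
  expect_equal(Kc, unname(Ko), tolerance = 1e-10)
  ## rigid translation lies in the null space
  u <- rep(c(1, 2, -1), 4)
  expect_lt(max(abs(Kc %*% u)), 1e-9 * max(abs(Kc)))
})

test_that("stiffness operators annihilate rigid-body translations", {
  mesh <- box_mesh(L = c(4, 2, 2), n = c(4, 2, 2))
  sys <- fem_system(mesh, elastic_params(), k_FE = 0)
  for (d in 1:3) {
    u <- numeric(3 * nrow(sys$nodes)); u[seq(d, length(u), 3)] <- 1
    expect_lt(max(abs(sys$K %*% u)), 1e-9 * max(abs(sys$K@x)))
  }
})

test_that("linear tets pass the uniform-strain patch test", {
  mesh <- box_mesh(L = c(3, 2, 2), n = c(3, 2, 2))
  mat <- elastic_params(4.518, 0.401)
  nodes <- mesh$nodes
  on_bnd <- nodes[, 1] %in% range(nodes[, 1]) |
    nodes[, 2] %in% range(nodes[, 2]) |
    nodes[, 3] %in% range(nodes[, 3])
  sys <- fem_system(mesh, mat, k_FE = 0, dirichlet_nodes = which(on_bnd))
  A <- matrix(c(1e-3, 2e-4, 0, 2e-4, -5e-4, 1e-4, 0, 1e-4, 3e-4), 3, 3)
  u_full <- as.vector(t(nodes %*% t(A)))
  sol <- solve_static(sys, dirichlet_full = u_full)
  ## displacement reproduced exactly everywhere
  expect_equal(sol$u, u_full, tolerance = 1e-8)
  ## stress uniform across all elements
  sig <- element_stresses(sys, sol$u)
  expect_lt(max(apply(sig, 2, function(s) diff(range(s)))), 1e-8)
})

test_that("cantilever tip deflection approaches Euler-Bernoulli", {
  mat <- elastic_params(4.518, 0.401)
  L <- 20; W <- 1; H <- 1; P <- 1e-3  # nN
  I <- W * H^3 / 12
  ref <- P * L^3 / (3 * mat$E * I)
  ## quadratic tets: within 5%
  mesh2 <- box_mesh(L = c(L, H, W), n = c(30, 3, 3))
  sys2 <- fem_system(mesh2, mat, k_FE = 0, order = 2)
  tipn <- which(abs(mesh2$nodes[, 1] - L) < 1e-9)
  f <- numeric(3 * nrow(sys2$nodes))
  f[3 * (tipn - 1) + 2] <- P / length(tipn)
  sol2 <- solve_static(sys2, f_ext = f)
  tipdef2 <- mean(sol2$u[3 * (tipn - 1) + 2])
  expect_equal(tipdef2, ref, tolerance = 0.05)
  ## linear tets at moderate density: within 15%
  mesh1 <- box_mesh(L = c(L, H, W), n = c(80, 10, 10))
  sys1 <- fem_system(mesh1, mat, k_FE = 0)
  tipn1 <- which(abs(mesh1$nodes[, 1] - L) < 1e-9)
  f1 <- numeric(3 * nrow(sys1$nodes))
  f1[3 * (tipn1 - 1) + 2] <- P / length(tipn1)
  sol1 <- solve_static(sys1, f_ext = f1)
  tipdef1 <- mean(sol1$u[3 * (tipn1 - 1) + 2])
  expect_equal(tipdef1, ref, tolerance = 0.15)
})

test_that("solved systems satisfy global equilibrium and energy identity", {
  mesh <- box_mesh(L = c(6, 2, 2), n = c(6, 2, 2))
  mat <- elastic_params()
  sys <- fem_system(mesh, mat, k_FE = 0)
  set.seed(7)
  f <- numeric(3 * nrow(sys$nodes))
  free_nodes <- setdiff(seq_len(nrow(sys$nodes)), sys$driver)
  pick <- sample(free_nodes, 10)
  f[3 * (pick - 1) + 1] <- runif(10, -1, 1) * 1e-3
  f[3 * (pick - 1) + 2] <- runif(10, -1, 1) * 1e-3
  sol <- solve_static(sys, f_ext = f)
  ## driver reaction equals the negative of all applied loads
  applied <- c(sum(f[seq(1, length(f), 3)]), sum(f[seq(2, length(f), 3)]),
               sum(f[seq(3, length(f), 3)]))
  expect_equal(sol$driver_reaction, -applied,
               tolerance = 1e-8 * max(abs(applied)))
  ## energy consistency for compatible loading (homogeneous Dirichlet)
  expect_equal(0.5 * sum(sol$u * as.numeric(sys$A %*% sol$u)),
               0.5 * sum(f * sol$u),
               tolerance = 1e-8)
  ## unloaded system stays at rest
  sol0 <- solve_static(sys)
  expect_equal(max(abs(sol0$u)), 0)
})

test_that("a lone penalty spring balances its load", {
  ## nearly rigid-free block held only by penalty springs: u -> f / k_FE
  mesh <- box_mesh(L = c(2, 2, 2), n = c(2, 2, 2))
  mesh$driver <- integer(0)
  mesh$bd <- list(seq_len(nrow(mesh$nodes)))
  mat <- elastic_params(E = 1e4, nu = 0.3)    # stiff -> moves as one body
  kfe <- 0.08
  sys <- fem_system(mesh, mat, k_FE = kfe, dirichlet_nodes = integer(0))
  n <- nrow(sys$nodes)
  f <- numeric(3 * n)
  f[seq(2, 3 * n, 3)] <- 0.01                  # nN per node, +y
  sol <- solve_static(sys, f_ext = f)
  expect_equal(mean(sol$u[seq(2, 3 * n, 3)]), 0.01 / kfe, tolerance = 1e-6)
})

test_that("stiffer penalty springs shrink bridging-domain displacements", {
  mesh <- box_mesh(L = c(6, 2, 2), n = c(6, 2, 2))
  nodes <- mesh$nodes
  mesh$bd <- list(which(abs(nodes[, 1] - 6) < 1e-9))
  mat <- elastic_params()
  f <- numeric(3 * nrow(nodes))
  f[3 * (mesh$bd[[1]] - 1) + 2] <- 1e-3
  norms <- vapply(c(0.01, 0.08, 0.5), function(k) {
    sys <- fem_system(mesh, mat, k_FE = k)
    sol <- solve_static(sys, f_ext = f)
    bd_dofs <- as.vector(outer(3 * (mesh$bd[[1]] - 1), 1:3, "+"))
    sqrt(sum(sol$u[bd_dofs]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})
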