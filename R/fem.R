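## Static linear-elastic finite elements on tetrahedral meshes.
## Units: nm (coordinates and displacements), GPa = nN/nm^2 (moduli),
## nN (forces), nN/nm (stiffness entries and penalty springs).

#' Assemble a static FEM system
#'
#' Assembles the global stiffness of small-strain isotropic elasticity over
#' the mesh tetrahedra (linear 4-node or quadratic 10-node elements), adds
#' the diagonal penalty operator `K^FE` (bridging-domain coupling springs)
#' on the bridging-domain degrees of freedom, applies the Dirichlet
#' constraint set, and caches a sparse Cholesky factorisation of the
#' constrained operator for repeated solves.
#'
#' @param mesh a [generate_mesh()] result (or any list with `nodes`,
#'   `tets`, `driver`, `bd`).
#' @param material an [elastic_params()] object.
#' @param k_FE FE-coupling (penalty) spring constant on bridging-domain
#'   nodes, nN/nm.
#' @param order element order: 1 (linear tets) or 2 (quadratic tets; edge
#'   mid-nodes are generated internally).
#' @param dirichlet_nodes nodes fully constrained in all three directions;
#'   defaults to the mesh driver set.
#' @return object of class `fem_system` with the operators, factorisation,
#'   and node bookkeeping.
#' @export
fem_system <- function(mesh, material, k_FE = 0.08, order = 1,
                       dirichlet_nodes = NULL) {
  stopifnot(inherits(material, "elastic_params"), k_FE >= 0,
            order %in% c(1, 2))
  if (is.null(dirichlet_nodes)) dirichlet_nodes <- mesh$driver
  bd <- mesh$bd %||% list()

  if (order == 1) {
    nodes <- mesh$nodes; tets <- mesh$tets
    tr <- .fem_assemble_p1_cpp(nodes, tets, material$lambda, material$mu)
  } else {
    p2 <- .p2_mesh(mesh$nodes, mesh$tets)
    nodes <- p2$nodes; tets <- p2$tets10
    tr <- .fem_assemble_p2(p2, material$lambda, material$mu)
  }
  ndof <- 3L * nrow(nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$v,
                            dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2, uplo = "U")

  bd_nodes <- unique(unlist(bd))
  pen <- numeric(ndof)
  if (length(bd_nodes) > 0)
    pen[as.vector(outer(3L * (bd_nodes - 1L), 1:3, "+"))] <- k_FE
  KFE <- Matrix::Diagonal(ndof, pen)
  A <- K + KFE

  cdof <- sort(as.vector(outer(3L * (dirichlet_nodes - 1L), 1:3, "+")))
  fdof <- setdiff(seq_len(ndof), cdof)
  if (length(cdof) == 0 && k_FE == 0)
    stop("singular system: no Dirichlet constraints and k_FE = 0",
         call. = FALSE)
  A_ff <- A[fdof, fdof]
  A_fc <- A[fdof, cdof, drop = FALSE]
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(A_ff),
                           LDL = FALSE, super = TRUE)

  structure(list(K = K, KFE = KFE, A = A, A_ff = A_ff, A_fc = A_fc,
                 chol = chol,
                 fdof = fdof, cdof = cdof,
                 nodes = nodes, tets = tets, order = order,
                 n_vertex = nrow(mesh$nodes),
                 driver = dirichlet_nodes, bd = bd,
                 material = material, k_FE = k_FE),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("<fem_system> %d nodes, %d tets (order %d), %d constrained dofs, k_FE %.3g nN/nm\n",
              nrow(x$nodes), nrow(x$tets), x$order, length(x$cdof), x$k_FE))
  invisible(x)
}

#' Solve one static FEM iteration
#'
#' Solves the penalised increment equation
#' `(K + K^FE) du = f_ext - K u_prev` under the Dirichlet constraints: the
#' driver nodes receive the prescribed increment `driver_disp` (a length-3
#' displacement, nm) and the anchor-point loads enter as nodal Neumann
#' forces. The penalty springs anchor bridging-domain nodes to their
#' positions at the start of the iteration, i.e. they restrain
#' per-iteration increments and vanish at convergence.
#'
#' @param sys a [fem_system()].
#' @param driver_disp length-3 prescribed displacement increment of the
#'   driver nodes for this iteration (zero after the first iteration of a
#'   load step), nm.
#' @param f_ext external load vector (length `3 * n_nodes`) or `NULL`, nN.
#' @param u_prev accumulated displacement from the undeformed mesh, nm
#'   (length `3 * n_nodes`); defaults to zero.
#' @param dirichlet_full optional full-length displacement vector whose
#'   entries at the constrained dofs are imposed verbatim (overrides
#'   `driver_disp`); used e.g. by uniform-strain patch tests.
#' @param tol relative residual tolerance for the solve.
#' @return list with `u` (updated total displacement), `du` (increment),
#'   `driver_reaction` (length-3 net constraint force on the driver set,
#'   nN), `reactions` (per-constrained-dof), `residual`.
#' @export
solve_static <- function(sys, driver_disp = c(0, 0, 0), f_ext = NULL,
                         u_prev = NULL, dirichlet_full = NULL,
                         tol = 1e-10) {
  ndof <- 3L * nrow(sys$nodes)
  if (is.null(f_ext)) f_ext <- numeric(ndof)
  if (is.null(u_prev)) u_prev <- numeric(ndof)
  stopifnot(length(f_ext) == ndof, length(u_prev) == ndof)

  b <- f_ext - as.numeric(sys$K %*% u_prev)
  raw <- as.vector(outer(3L * (sys$driver - 1L), 1:3, "+"))
  if (is.null(dirichlet_full)) {
    ## cdof is sorted; build the constrained values accordingly
    dmap <- setNames(rep(0, length(sys$cdof)), sys$cdof)
    dmap[as.character(raw)] <- rep(driver_disp, each = length(sys$driver))
    dc <- unname(dmap)
  } else {
    dc <- dirichlet_full[sys$cdof]
  }

  rhs <- b[sys$fdof] - as.numeric(sys$A_fc %*% dc)
  du_f <- as.numeric(Matrix::solve(sys$chol, rhs, system = "A"))
  du <- numeric(ndof)
  du[sys$fdof] <- du_f
  du[sys$cdof] <- dc

  res <- as.numeric(sys$A_ff %*% du_f) - rhs
  rel <- sqrt(sum(res^2)) /
    max(sqrt(sum(rhs^2)), sqrt(sum(b[sys$fdof]^2)), 1e-12)
  if (rel > tol * 1e4)
    warning(sprintf("FEM solve residual %.2e above tolerance", rel),
            call. = FALSE)

  u <- u_prev + du
  ## constraint reactions: internal force minus applied load at fixed dofs
  r_all <- as.numeric(sys$K %*% u) + as.numeric(sys$KFE %*% du) - f_ext
  reac <- r_all[sys$cdof]
  dr <- colSums(matrix(r_all[raw], ncol = 3,
                       byrow = FALSE))
  list(u = u, du = du, driver_reaction = dr, reactions = reac,
       residual = rel)
}

#' Net driver constraint force
#'
#' Sum of the constraint reactions over the driver node set for a solved
#' state (`solve_static()` already reports it; this recomputes from a
#' displacement field).
#'
#' @param sys a [fem_system()].
#' @param u total displacement vector, nm.
#' @param f_ext external load vector, nN (default zero).
#' @return length-3 force, nN (force the driver constraint applies to the
#'   structure).
#' @export
driver_reaction <- function(sys, u, f_ext = NULL) {
  ndof <- 3L * nrow(sys$nodes)
  if (is.null(f_ext)) f_ext <- numeric(ndof)
  r_all <- as.numeric(sys$K %*% u) - f_ext
  raw <- as.vector(outer(3L * (sys$driver - 1L), 1:3, "+"))
  colSums(matrix(r_all[raw], ncol = 3))
}

#' Per-element stresses (linear tets)
#'
#' Constant stress per element from a displacement field; used e.g. by the
#' uniform-strain patch test.
#'
#' @param sys an order-1 [fem_system()].
#' @param u displacement vector, nm.
#' @return m x 6 matrix of Voigt stresses (xx, yy, zz, xy, yz, xz), GPa.
#' @export
element_stresses <- function(sys, u) {
  stopifnot(sys$order == 1)
  nodes <- sys$nodes; tets <- sys$tets
  lam <- sys$material$lambda; mu <- sys$material$mu
  m <- nrow(tets)
  out <- matrix(0, m, 6)
  for (t in seq_len(m)) {
    nd <- tets[t, ]
    X <- nodes[nd, ]
    J <- t(X[2:4, ]) - X[1, ]
    invJ <- solve(J)
    g <- rbind(-colSums(invJ), invJ)   # rows: dN_a/dx
    ue <- matrix(u[as.vector(t(outer(3 * (nd - 1), 1:3, "+")))], ncol = 3,
                 byrow = TRUE)
    gradu <- t(ue) %*% g               # du_i/dx_j
    eps <- (gradu + t(gradu)) / 2
    tr <- sum(diag(eps))
    sig <- lam * tr * diag(3) + 2 * mu * eps
    out[t, ] <- c(sig[1, 1], sig[2, 2], sig[3, 3], sig[1, 2], sig[2, 3],
                  sig[1, 3])
  }
  out
}

## ---- quadratic (10-node) tetrahedra -------------------------------------

## add unique edge mid-nodes; tets10 columns: 4 corners then mid-nodes of
## edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
.p2_mesh <- function(nodes, tets) {
  m <- nrow(tets)
  epairs <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                  tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  a <- pmin(epairs[, 1], epairs[, 2]); b <- pmax(epairs[, 1], epairs[, 2])
  key <- paste(a, b)
  uk <- !duplicated(key)
  eid <- match(key, key[uk])
  mids <- (nodes[a[uk], , drop = FALSE] + nodes[b[uk], , drop = FALSE]) / 2
  n0 <- nrow(nodes)
  tets10 <- cbind(tets, matrix(n0 + eid, nrow = m, ncol = 6))
  list(nodes = rbind(nodes, mids), tets10 = tets10, n_vertex = n0)
}

## 4-point Gauss rule on the reference tet (degree 2)
.tet_gauss4 <- local({
  a <- 0.5854101966249685; b <- 0.1381966011250105
  list(pts = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b),
                   c(b, b, b, a)),
       w = rep(0.25, 4))
})

.fem_assemble_p2 <- function(p2, lambda, mu) {
  nodes <- p2$nodes; tets <- p2$tets10
  m <- nrow(tets)
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  qp <- .tet_gauss4
  ## edge list in barycentric index pairs, matching .p2_mesh column order
  ed <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  II <- vector("list", m); JJ <- vector("list", m); VV <- vector("list", m)
  idx12 <- function(nd) as.vector(t(outer(3 * (nd - 1), 1:3, "+")))
  for (t in seq_len(m)) {
    nd <- tets[t, ]
    X <- nodes[nd[1:4], ]
    J <- t(X[2:4, ]) - X[1, ]
    detJ <- det(J)
    if (detJ <= 0) stop("inverted element Jacobian in element ", t,
                        call. = FALSE)
    vol <- detJ / 6
    invJ <- solve(J)
    gl <- rbind(-colSums(invJ), invJ)  # grad lambda_a (4 x 3), constant
    Ke <- matrix(0, 30, 30)
    for (q in 1:4) {
      lam4 <- qp$pts[q, ]
      ## shape-function gradients (10 x 3)
      g <- matrix(0, 10, 3)
      for (aa in 1:4) g[aa, ] <- (4 * lam4[aa] - 1) * gl[aa, ]
      for (e in 1:6) {
        aa <- ed[e, 1]; bb <- ed[e, 2]
        g[4 + e, ] <- 4 * (lam4[bb] * gl[aa, ] + lam4[aa] * gl[bb, ])
      }
      B <- matrix(0, 6, 30)
      c0 <- 3 * (0:9)
      B[1, c0 + 1] <- g[, 1]
      B[2, c0 + 2] <- g[, 2]
      B[3, c0 + 3] <- g[, 3]
      B[4, c0 + 1] <- g[, 2]; B[4, c0 + 2] <- g[, 1]
      B[5, c0 + 2] <- g[, 3]; B[5, c0 + 3] <- g[, 2]
      B[6, c0 + 1] <- g[, 3]; B[6, c0 + 3] <- g[, 1]
      Ke <- Ke + crossprod(B, D %*% B) * (vol * qp$w[q])
    }
    gi <- idx12(nd)
    II[[t]] <- rep(gi, times = 30)
    JJ[[t]] <- rep(gi, each = 30)
    VV[[t]] <- as.vector(Ke)
  }
  list(i = unlist(II), j = unlist(JJ), v = unlist(VV))
}

#' Structured box mesh
#'
#' Regular tetrahedral mesh of an axis-aligned box (Kuhn subdivision of a
#' voxel grid); used by the FEM benchmarks (patch test, cantilever).
#'
#' @param L length-3 box dimensions, nm.
#' @param n length-3 integer voxel counts.
#' @return a mesh list compatible with [fem_system()] (with empty `bd` and
#'   `driver` on the x = 0 face).
#' @export
box_mesh <- function(L = c(20, 1, 1), n = c(40, 3, 3)) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  xs <- seq(0, L[1], length.out = nx + 1)
  ys <- seq(0, L[2], length.out = ny + 1)
  zs <- seq(0, L[3], length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(ix, iy, iz) 1L + ix + (nx + 1L) * (iy + (ny + 1L) * iz)
  g <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1), iz = 0:(nz - 1))
  off <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1), c(0, 0, 1, 1, 0, 0, 1, 1),
               c(0, 0, 0, 0, 1, 1, 1, 1))
  corners <- sapply(1:8, function(c8)
    nid(g$ix + off[c8, 1], g$iy + off[c8, 2], g$iz + off[c8, 3]))
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  tets <- do.call(rbind, lapply(1:6, function(k) corners[, kuhn[k, ]]))
  v <- .tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  nodes <- unname(as.matrix(nodes))
  list(nodes = nodes, tets = tets,
       driver = which(abs(nodes[, 1]) < 1e-12), bd = list())
}
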