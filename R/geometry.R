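## Procedural construction of the branched seta: two guiding parabolas fix
## the envelope, branching points are midpoints of equidistant intervals
## between them, and the solid is the union of tapering circular branches
## (frusta) swept along the skeleton edges, meshed into tetrahedra.
##
## Coordinates: Y is the substrate normal (+Y is the pull direction), X runs
## along the seta elevation toward spatula 1, Z is lateral. The origin lies
## on the substrate surface plane.

#' Geometric parameters of the seta
#'
#' Bundles and validates the parameters that define the branched seta
#' envelope and its finite element mesh. Defaults describe the full-scale
#' seta: total height 22.8 um, base width 13.5 um, inclination 30 degrees,
#' four branching levels ending in 16 spatula-bearing tips.
#'
#' @param H0_um total seta height (top truncation plane), micrometres.
#' @param D0_um seta base width, micrometres. The two guiding parabolas have
#'   vertex half-widths `C1 = 0.5*D0` and `1.5*D0`, with `C2 = C1*tan(alpha)`.
#' @param alpha_deg seta inclination angle in degrees, strictly in (0, 90).
#' @param R_sp_nm spatula shaft diameter in nm; the width of the finest
#'   branch tips.
#' @param eta height-scaling parameter (> 1): branching heights follow
#'   `H_i = eta^(n_levels - i) * H_sp`.
#' @param gamma width-scaling parameter (> 1): branch widths follow
#'   `W_i = gamma^(n_levels + 1 - i) * R_sp`. The default equals `eta`; the
#'   full-scale value is uncertain and should be treated as a model choice.
#' @param H_sp_um spatula height (final tiny FE branch plus molecular
#'   spatula), micrometres.
#' @param n_levels number of branching levels; the seta ends in
#'   `2^n_levels` tips.
#' @param mesh_h_nm target tetrahedral mesh resolution (voxel edge length) in
#'   nm; default `NULL` picks one third of the finest branch width.
#' @param tip_trunc_frac fraction of `H_sp` (measured from the substrate)
#'   removed from each final FE branch to make room for the molecular
#'   spatula.
#' @param bd_frac fraction of each truncated final branch (from its bottom
#'   end) whose mesh nodes form that spatula's bridging-domain node set.
#' @return an object of class `geometry_params` (a validated named list, all
#'   lengths converted to nm).
#' @export
geometry_params <- function(H0_um = 22.8, D0_um = 13.5, alpha_deg = 30,
                            R_sp_nm = 50, eta = 2.417, gamma = 2.417,
                            H_sp_um = 0.67, n_levels = 4,
                            mesh_h_nm = NULL, tip_trunc_frac = 0.5,
                            bd_frac = 0.4) {
  stopifnot(H0_um > 0, D0_um > 0, R_sp_nm > 0, H_sp_um > 0,
            n_levels >= 1, n_levels == round(n_levels),
            tip_trunc_frac > 0, tip_trunc_frac < 1,
            bd_frac > 0, bd_frac <= 1)
  if (!(alpha_deg > 0 && alpha_deg < 90))
    stop("alpha_deg must lie strictly between 0 and 90 degrees", call. = FALSE)
  if (eta <= 1) stop("eta must be > 1", call. = FALSE)
  if (gamma <= 1) stop("gamma must be > 1", call. = FALSE)
  p <- list(
    H0 = H0_um * 1e3, D0 = D0_um * 1e3, alpha = alpha_deg * pi / 180,
    R_sp = R_sp_nm, eta = eta, gamma = gamma, H_sp = H_sp_um * 1e3,
    n_levels = as.integer(n_levels),
    mesh_h = mesh_h_nm, tip_trunc_frac = tip_trunc_frac, bd_frac = bd_frac
  )
  p$C1 <- c(0.5, 1.5) * p$D0
  p$C2 <- p$C1 * tan(p$alpha)
  class(p) <- "geometry_params"
  p
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("<geometry_params>\n")
  cat(sprintf("  H0 %.3g um, D0 %.3g um, alpha %.1f deg, %d levels -> %d tips\n",
              x$H0 / 1e3, x$D0 / 1e3, x$alpha * 180 / pi,
              x$n_levels, 2L^x$n_levels))
  cat(sprintf("  eta %.3f, gamma %.3f, H_sp %.3g um, R_sp %.0f nm\n",
              x$eta, x$gamma, x$H_sp / 1e3, x$R_sp))
  invisible(x)
}

#' Guiding parabola of the seta envelope
#'
#' Evaluates the positive branch `x = C1 * sqrt(1 + y^2 / C2^2)` of the
#' hyperbolic envelope curve `x^2/C1^2 - y^2/C2^2 = 1` that bounds the seta
#' skeleton.
#'
#' @param y height(s) above the substrate, nm; must be non-negative.
#' @param C1,C2 curve parameters, nm; both strictly positive.
#' @return x coordinate(s) on the curve, nm.
#' @export
parabola_x <- function(y, C1, C2) {
  if (C1 <= 0 || C2 <= 0) stop("C1 and C2 must be positive", call. = FALSE)
  if (any(y < 0)) stop("y must be non-negative", call. = FALSE)
  C1 * sqrt(1 + (y / C2)^2)
}

#' Branching heights
#'
#' Heights of the branching levels, `H_i = eta^(n_levels - i) * H_sp` for
#' `i = 0..n_levels`. `H_0` is the (formula) total height and
#' `H_{n_levels} = H_sp`.
#'
#' @param params a [geometry_params()] object.
#' @return named numeric vector of heights in nm (`H0`, `H1`, ...).
#' @export
branch_heights <- function(params) {
  i <- 0:params$n_levels
  setNames(params$eta^(params$n_levels - i) * params$H_sp, paste0("H", i))
}

#' Branch widths
#'
#' Cross-sectional widths of the branches,
#' `W_i = gamma^(n_levels + 1 - i) * R_sp` for `i = 0..(n_levels + 1)`;
#' the final tips have width `R_sp`.
#'
#' @param params a [geometry_params()] object.
#' @return named numeric vector of widths in nm (`W0`, `W1`, ...).
#' @export
branch_widths <- function(params) {
  i <- 0:(params$n_levels + 1)
  setNames(params$gamma^(params$n_levels + 1 - i) * params$R_sp,
           paste0("W", i))
}

## x-interval between the two parabolas at height y (nm)
.envelope_segment <- function(params, y) {
  c(parabola_x(y, params$C1[1], params$C2[1]),
    parabola_x(y, params$C1[2], params$C2[2]))
}

## midpoints of 2^(i-1) equidistant intervals of [lo, hi]
.interval_midpoints <- function(lo, hi, n_intervals) {
  lo + ((seq_len(n_intervals)) - 0.5) * (hi - lo) / n_intervals
}

#' Build the seta skeleton
#'
#' Distributes branching points between the two guiding parabolas: at each
#' branching height the horizontal segment between the parabolas is divided
#' into `2^(i-1)` equidistant intervals whose midpoints are the level-i
#' branching points. Tips (level `n_levels + 1`) sit on the substrate plane
#' (y = 0) at the midpoints of `2^n_levels` intervals; the final branches
#' are truncated at `tip_trunc_frac * H_sp` to make room for the molecular
#' spatulae. Joining the points yields the edge tree; each edge carries a
#' linearly tapering width between consecutive level widths.
#'
#' @param params a [geometry_params()] object.
#' @return an object of class `seta_skeleton`: a list with `points`
#'   (tibble: id, level, x, y, z), `edges` (tibble: from, to, level, r_top,
#'   r_bot), `tips` (tibble per spatula: id, point id of the truncated tip,
#'   full tip coordinates at y = 0, branch axis unit vector), plus the
#'   parameters.
#' @export
build_skeleton <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  n  <- params$n_levels
  Hi <- branch_heights(params)
  Wi <- branch_widths(params)

  pts <- list(); pid <- 0L
  add_pt <- function(level, x, y) {
    pid <<- pid + 1L
    pts[[pid]] <<- c(id = pid, level = level, x = x, y = y, z = 0)
    pid
  }

  ## apex above the truncation plane so the mesh can be cut cleanly at H0
  y_apex <- 1.05 * params$H0
  seg <- .envelope_segment(params, y_apex)
  if (seg[2] <= seg[1])
    stop("parabolas do not bracket a positive-length segment at the apex",
         call. = FALSE)
  apex <- add_pt(0L, mean(seg), y_apex)

  level_ids <- vector("list", n + 1L)
  level_ids[[1]] <- apex
  for (i in seq_len(n)) {
    y <- Hi[[paste0("H", i)]]
    seg <- .envelope_segment(params, y)
    if (seg[2] <= seg[1])
      stop("parabolas do not bracket a positive-length segment at level ", i,
           call. = FALSE)
    xs <- .interval_midpoints(seg[1], seg[2], 2L^(i - 1L))
    level_ids[[i + 1L]] <- vapply(xs, function(x) add_pt(i, x, y), integer(1))
  }

  ## full tips at y = 0, truncated tip points on the tip edges
  seg0 <- .envelope_segment(params, 0)
  tip_x <- .interval_midpoints(seg0[1], seg0[2], 2L^n)
  y_tr  <- params$tip_trunc_frac * params$H_sp

  edges <- list(); eid <- 0L
  add_edge <- function(from, to, level, r_top, r_bot) {
    eid <<- eid + 1L
    edges[[eid]] <<- c(from = from, to = to, level = level,
                       r_top = r_top, r_bot = r_bot)
  }
  ## internal edges: level i point -> its two children at level i+1
  ## (children j maps to parents ceiling(j/2) in x-sorted order; midpoint
  ## nesting guarantees children lie inside the parent's interval)
  for (i in 0:(n - 1L)) {
    parents  <- level_ids[[i + 1L]]
    children <- level_ids[[i + 2L]]
    for (j in seq_along(children)) {
      parent <- parents[[if (i == 0L) 1L else ceiling(j / 2)]]
      add_edge(parent, children[[j]], i, Wi[[paste0("W", i)]] / 2,
               Wi[[paste0("W", i + 1L)]] / 2)
    }
  }

  ## tip edges: level-n point -> truncated tip, width tapering toward R_sp
  pts_mat <- do.call(rbind, pts)
  tip_rows <- list()
  parents <- level_ids[[n + 1L]]
  r_top <- Wi[[paste0("W", n)]] / 2
  r_bot_full <- Wi[[paste0("W", n + 1L)]] / 2
  for (s in seq_len(2L^n)) {
    parent <- parents[[ceiling(s / 2)]]
    p0 <- pts_mat[parent, c("x", "y", "z")]
    p1 <- c(tip_x[s], 0, 0)
    tfrac <- (p0[2] - y_tr) / p0[2]          # parameter of the cut plane
    p_cut <- p0 + tfrac * (p1 - p0)
    r_cut <- r_top + tfrac * (r_bot_full - r_top)
    cut_id <- add_pt(n + 1L, p_cut[1], p_cut[2])
    pts_mat <- do.call(rbind, pts)
    add_edge(parent, cut_id, n, r_top, r_cut)
    axis <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    tip_rows[[s]] <- tibble::tibble(
      spatula = s, point = cut_id,
      x_full = p1[1], y_full = 0,
      x_cut = p_cut[1], y_cut = p_cut[2], r_cut = r_cut,
      axis_x = axis[1], axis_y = axis[2], axis_z = axis[3])
  }

  pts_df <- tibble::as_tibble(as.data.frame(do.call(rbind, pts)))
  pts_df$id <- as.integer(pts_df$id); pts_df$level <- as.integer(pts_df$level)
  edg_df <- tibble::as_tibble(as.data.frame(do.call(rbind, edges)))
  edg_df$from <- as.integer(edg_df$from); edg_df$to <- as.integer(edg_df$to)
  edg_df$level <- as.integer(edg_df$level)

  ## spatula 1 sits at the largest x (the +X axis points toward it)
  tips <- dplyr::arrange(dplyr::bind_rows(tip_rows), dplyr::desc(.data$x_full))
  tips$spatula <- seq_len(nrow(tips))
  structure(list(points = pts_df, edges = edg_df,
                 tips = tips, params = params),
            class = "seta_skeleton")
}

#' @export
print.seta_skeleton <- function(x, ...) {
  cat("<seta_skeleton>\n")
  cat(sprintf("  %d points, %d edges, %d tips\n",
              nrow(x$points), nrow(x$edges), nrow(x$tips)))
  invisible(x)
}

## squared distance of points P (n x 3) to segment a->b together with the
## clamped projection parameter
.seg_project <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
          (P[, 3] - a[3]) * ab[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  dx <- P[, 1] - (a[1] + t * ab[1])
  dy <- P[, 2] - (a[2] + t * ab[2])
  dz <- P[, 3] - (a[3] + t * ab[3])
  list(t = t, d2 = dx * dx + dy * dy + dz * dz)
}

#' Generate the tetrahedral finite element mesh of the seta
#'
#' Meshes the union of tapering circular branches swept along the skeleton
#' edges. The solid is discretised on a regular voxel grid aligned with the
#' top truncation plane; every voxel whose centre lies inside a branch is
#' split into six face-conforming tetrahedra (Kuhn subdivision). The portion
#' above `H0` is removed (its cut plane carries the driver node set) and the
#' lower part of each final branch is absent by construction (truncated
#' skeleton), with the bottom `bd_frac` of each remaining final branch
#' providing that spatula's bridging-domain node set.
#'
#' @param skeleton a [build_skeleton()] result.
#' @param h voxel edge length in nm; default `params$mesh_h` or one third of
#'   the finest branch width.
#' @return an object of class `seta_mesh`: list with `nodes` (n x 3 matrix,
#'   nm), `tets` (m x 4 integer matrix, positively oriented), `driver`
#'   (node indices on the top truncation plane), `bd` (list of
#'   bridging-domain node index vectors, one per spatula), `h`, and the
#'   originating `skeleton`.
#' @export
generate_mesh <- function(skeleton, h = NULL) {
  stopifnot(inherits(skeleton, "seta_skeleton"))
  params <- skeleton$params
  if (is.null(h)) h <- params$mesh_h
  if (is.null(h)) h <- min(branch_widths(params)) / 3
  stopifnot(h > 0)

  pts <- as.matrix(skeleton$points[, c("x", "y", "z")])
  edges <- skeleton$edges
  rmax <- max(edges$r_top)

  ## grid anchored to the geometry: a node plane lies exactly at y = H0
  H0 <- params$H0
  ylo <- min(pts[, 2]) - h
  yhi <- max(pts[, 2]) + rmax + h
  ky_lo <- floor((H0 - ylo) / h); ky_hi <- ceiling((yhi - H0) / h)
  y0 <- H0 - ky_lo * h
  Ny <- ky_lo + ky_hi
  xlo <- min(pts[, 1]) - rmax - h; xhi <- max(pts[, 1]) + rmax + h
  x0 <- xlo; Nx <- ceiling((xhi - xlo) / h)
  zmax <- rmax + h
  Nz <- ceiling(2 * zmax / h)
  z0 <- -Nz * h / 2

  ## mark voxels whose centre lies inside the union of frusta
  inside <- logical(Nx * Ny * Nz)
  for (e in seq_len(nrow(edges))) {
    a <- pts[edges$from[e], ]; b <- pts[edges$to[e], ]
    ra <- edges$r_top[e]; rb <- edges$r_bot[e]
    r_hi <- max(ra, rb)
    ix <- max(0L, floor((min(a[1], b[1]) - r_hi - x0) / h)) :
      min(Nx - 1L, ceiling((max(a[1], b[1]) + r_hi - x0) / h))
    iy <- max(0L, floor((min(a[2], b[2]) - r_hi - y0) / h)) :
      min(Ny - 1L, ceiling((max(a[2], b[2]) + r_hi - y0) / h))
    iz <- max(0L, floor((-r_hi - z0) / h)) :
      min(Nz - 1L, ceiling((r_hi - z0) / h))
    g <- expand.grid(ix = ix, iy = iy, iz = iz)
    P <- cbind(x0 + (g$ix + 0.5) * h,
               y0 + (g$iy + 0.5) * h,
               z0 + (g$iz + 0.5) * h)
    pr <- .seg_project(P, a, b)
    rt <- ra + pr$t * (rb - ra)
    ok <- pr$d2 <= rt * rt
    if (any(ok)) {
      idx <- g$ix[ok] + Nx * (g$iy[ok] + Ny * g$iz[ok]) + 1L
      inside[idx] <- TRUE
    }
  }

  ## drop voxels above the truncation plane (centre above y = H0)
  ci <- which(inside) - 1L
  cix <- ci %% Nx
  ciy <- (ci %/% Nx) %% Ny
  ciz <- ci %/% (Nx * Ny)
  cy <- y0 + (ciy + 0.5) * h
  keep <- cy < H0
  cix <- cix[keep]; ciy <- ciy[keep]; ciz <- ciz[keep]
  n_vox <- length(cix)
  if (n_vox == 0L) stop("mesh resolution too coarse: no voxels", call. = FALSE)

  ## corner ids on the (Nx+1)(Ny+1)(Nz+1) point grid
  corner_key <- function(ix, iy, iz)
    ix + (Nx + 1) * (iy + (Ny + 1) * iz) + 1
  off <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
               c(0, 0, 1, 1, 0, 0, 1, 1),
               c(0, 0, 0, 0, 1, 1, 1, 1))
  corners <- matrix(0, nrow = n_vox, ncol = 8)
  for (c8 in 1:8) {
    corners[, c8] <- corner_key(cix + off[c8, 1], ciy + off[c8, 2],
                                ciz + off[c8, 3])
  }
  ## Kuhn subdivision: six tets around the 000 -> 111 diagonal; identical
  ## in every voxel, hence face-conforming across voxel boundaries
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  tets_key <- do.call(rbind, lapply(1:6, function(k) corners[, kuhn[k, ], drop = FALSE]))

  keys <- sort(unique(as.vector(tets_key)))
  tets <- matrix(match(as.vector(tets_key), keys), ncol = 4)
  k0 <- keys - 1
  nodes <- cbind(x0 + (k0 %% (Nx + 1)) * h,
                 y0 + ((k0 %/% (Nx + 1)) %% (Ny + 1)) * h,
                 z0 + (k0 %/% ((Nx + 1) * (Ny + 1))) * h)

  ## orient all tets positively
  v <- .tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  v <- abs(v)
  if (any(v <= 0))
    stop("degenerate (zero-volume) elements: ",
         paste(head(which(v <= 0), 5), collapse = ", "), call. = FALSE)

  ## keep the largest connected component
  comp <- cc_label_tets(nrow(nodes), tets)
  main <- as.integer(names(which.max(table(comp$node_comp))))
  keep_t <- comp$tet_comp == main
  tets <- tets[keep_t, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  nodes <- nodes[used, , drop = FALSE]

  ## node sets
  driver <- which(abs(nodes[, 2] - H0) < 1e-6 * max(1, H0))
  if (length(driver) == 0L)
    stop("no driver nodes found on the truncation plane", call. = FALSE)
  bd <- vector("list", nrow(skeleton$tips))
  for (s in seq_len(nrow(skeleton$tips))) {
    tip <- skeleton$tips[s, ]
    erow <- edges[edges$to == tip$point, ]
    a <- pts[erow$from, ]; b <- pts[erow$to, ]
    pr <- .seg_project(nodes, a, b)
    rt <- erow$r_top + pr$t * (erow$r_bot - erow$r_top)
    sel <- which(pr$t >= 1 - params$bd_frac & pr$d2 <= (rt + 0.75 * h)^2)
    if (length(sel) == 0L)
      stop("empty bridging-domain node set for spatula ", s,
           " (mesh too coarse for the final branches)", call. = FALSE)
    bd[[s]] <- setdiff(sel, driver)
  }
  ## bridging domains must be mutually disjoint
  all_bd <- unlist(bd)
  if (anyDuplicated(all_bd)) {
    dup <- unique(all_bd[duplicated(all_bd)])
    for (s in seq_along(bd)) bd[[s]] <- setdiff(bd[[s]], dup)
  }

  structure(list(nodes = nodes, tets = tets, h = h,
                 driver = driver, bd = bd, skeleton = skeleton),
            class = "seta_mesh")
}

#' @export
print.seta_mesh <- function(x, ...) {
  cat("<seta_mesh>\n")
  cat(sprintf("  %d nodes, %d tets (h = %.3g nm)\n",
              nrow(x$nodes), nrow(x$tets), x$h))
  cat(sprintf("  %d driver nodes, %d bridging domains (%s APs)\n",
              length(x$driver), length(x$bd),
              paste(range(lengths(x$bd)), collapse = "-")))
  invisible(x)
}

.tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Total mesh volume
#'
#' @param mesh a [generate_mesh()] result.
#' @return total volume of all tetrahedra, nm^3.
#' @export
mesh_volume <- function(mesh) sum(abs(.tet_volumes(mesh$nodes, mesh$tets)))

## Euler characteristic (V - E + F) of the boundary surface; 2 for a single
## genus-0 shell. Used by mesh sanity checks.
mesh_boundary_euler <- function(mesh) {
  tf <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
              mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  tf <- t(apply(tf, 1, sort))
  key <- paste(tf[, 1], tf[, 2], tf[, 3])
  bnd <- tf[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  ed <- rbind(bnd[, c(1, 2)], bnd[, c(1, 3)], bnd[, c(2, 3)])
  ek <- unique(paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  length(unique(as.vector(bnd))) - length(ek) + nrow(bnd)
}

## Numeric volume of the union of frusta (independent of the mesher): dense
## midpoint quadrature on a grid of spacing hq.
skeleton_solid_volume <- function(skeleton, hq) {
  params <- skeleton$params
  pts <- as.matrix(skeleton$points[, c("x", "y", "z")])
  edges <- skeleton$edges
  rmax <- max(edges$r_top)
  xr <- range(pts[, 1]) + c(-1, 1) * (rmax + hq)
  yr <- c(min(pts[, 2]) - hq, params$H0)
  zr <- c(-1, 1) * (rmax + hq)
  xs <- seq(xr[1] + hq / 2, xr[2], by = hq)
  zs <- seq(zr[1] + hq / 2, zr[2], by = hq)
  n_in <- 0
  ## slab by slab in y to bound memory
  ys <- seq(yr[1] + hq / 2, yr[2], by = hq)
  for (y in ys) {
    P <- cbind(rep(xs, times = length(zs)), y, rep(zs, each = length(xs)))
    ok <- rep(FALSE, nrow(P))
    for (e in seq_len(nrow(edges))) {
      a <- pts[edges$from[e], ]; b <- pts[edges$to[e], ]
      if (y < min(a[2], b[2]) - edges$r_top[e] ||
          y > max(a[2], b[2]) + edges$r_top[e]) next
      pr <- .seg_project(P, a, b)
      rt <- edges$r_top[e] + pr$t * (edges$r_bot[e] - edges$r_top[e])
      ok <- ok | (pr$d2 <= rt * rt)
    }
    n_in <- n_in + sum(ok)
  }
  n_in * hq^3
}

#' Export a tetrahedral mesh as legacy ASCII VTK
#'
#' Writes nodes, tetrahedra and node-set labels (driver = -1, bridging
#' domain s = s, other = 0) as an unstructured grid readable by ParaView.
#'
#' @param mesh a [generate_mesh()] result.
#' @param path output file path (`.vtk`).
#' @param point_data optional named list of per-node numeric vectors to
#'   append as additional point data arrays.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "seta mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(r, collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(mesh$tets - 1L, 1, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  labels <- numeric(n)
  labels[mesh$driver] <- -1
  for (s in seq_along(mesh$bd)) labels[mesh$bd[[s]]] <- s
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS node_set double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(labels), con)
  for (nm in names(point_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(point_data[[nm]]), con)
  }
  invisible(path)
}

#' Export a skeleton as JSON
#'
#' @param skeleton a [build_skeleton()] result.
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_skeleton_json <- function(skeleton, path) {
  jsonlite::write_json(
    list(points = skeleton$points, edges = skeleton$edges,
         tips = skeleton$tips),
    path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(path)
}
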