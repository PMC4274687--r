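# Cylindrical Doo-Sabin subdivision surface: control net, radial deformation,
# refinement with explicit weight tracking (every refined vertex is a fixed
# linear combination of control points, which gives the deformation Jacobian
# by the chain rule), and fixed-parameterization surface sampling.

#' Create the default cylindrical control mesh
#'
#' Builds the control net of the LVOT/aortic-root surface model: `rings`
#' circles of `points_per_ring` uniformly distributed control points on a
#' cylinder whose long axis is the model z-axis, centred so the annulus disc
#' plane is z = 0. Each control point carries a radial (unit, zero-z)
#' deformation direction; local deformation displaces control points along
#' these directions only, which maximizes shape change per degree of freedom.
#'
#' @param diameter Initial cylinder diameter in mm.
#' @param length Cylinder length in mm (rings are evenly spaced over it).
#' @param rings Number of control-point circles (default 5).
#' @param points_per_ring Control points per circle (default 6).
#' @param ring_scale Relative radius of each ring (length `rings`, default
#'   all 1: a straight cylinder of diameter `diameter`). The tracking
#'   pipeline uses an aortic-root-shaped template (see
#'   [root_template_scale()]): a waist at the annulus plane with the sinus
#'   bulge above it, which anchors the model axially during the stiff pose
#'   phase (a straight cylinder leaves axial translation unobservable, since
#'   all its surface normals are exactly radial).
#' @return An object of class `ds_mesh` with elements `points` (n x 3 matrix,
#'   mm), `dirs` (n x 3 unit radial deformation directions), `rings`,
#'   `points_per_ring`, `length`, `diameter` and `disc_radius` (radius of the
#'   undeformed limit surface at z = 0, used for the annulus disc).
#' @examples
#' m <- ds_mesh(20, 40)
#' nrow(m$points)  # 30 control points
#' @export
ds_mesh <- function(diameter = 25, length = 40, rings = 5L, points_per_ring = 6L,
                    ring_scale = rep(1, rings)) {
  if (!is.finite(diameter) || diameter <= 0) stop("'diameter' must be positive")
  if (!is.finite(length) || length <= 0) stop("'length' must be positive")
  rings <- as.integer(rings); points_per_ring <- as.integer(points_per_ring)
  if (rings < 3L || points_per_ring < 3L) stop("need >= 3 rings and >= 3 points per ring")
  if (length(ring_scale) != rings || any(ring_scale <= 0))
    stop("'ring_scale' must give a positive relative radius per ring")
  r <- diameter / 2
  z <- seq(-length / 2, length / 2, length.out = rings)
  ang <- 2 * pi * (seq_len(points_per_ring) - 1L) / points_per_ring
  # column-major over rings: index (i, j) -> (j - 1) * rings + i
  pts <- matrix(0, rings * points_per_ring, 3)
  dirs <- matrix(0, rings * points_per_ring, 3)
  for (j in seq_len(points_per_ring)) {
    for (i in seq_len(rings)) {
      k <- (j - 1L) * rings + i
      pts[k, ] <- c(r * ring_scale[i] * cos(ang[j]), r * ring_scale[i] * sin(ang[j]), z[i])
      dirs[k, ] <- c(cos(ang[j]), sin(ang[j]), 0)
    }
  }
  m <- structure(list(points = pts, dirs = dirs, rings = rings,
                      points_per_ring = points_per_ring,
                      diameter = diameter, length = length),
                 class = "ds_mesh")
  m$disc_radius <- .ds_mid_radius(m)
  m
}

#' Aortic-root shape template for the initial surface
#'
#' Relative ring radii (bottom to top: LVOT, sub-annular, annulus, sinus of
#' Valsalva, sinotubular/ascending) of the initial model, from textbook root
#' proportions: the sinus bulges to about 1.3 times the annulus diameter and
#' the sinotubular junction to about 1.1. Besides being anatomically
#' sensible, the waist-and-bulge profile makes the axial position of the
#' model observable to the rigid (stiff) tracking phase.
#'
#' @return Numeric vector of length 5.
#' @export
root_template_scale <- function() c(1.02, 1, 1, 1.3, 1.1)

#' @export
print.ds_mesh <- function(x, ...) {
  cat("Cylindrical Doo-Sabin control mesh:", x$rings, "rings x",
      x$points_per_ring, "points;",
      sprintf("diameter %.1f mm, length %.1f mm, disc radius %.2f mm\n",
              x$diameter, x$length, x$disc_radius))
  invisible(x)
}

#' Apply local radial deformation to a control mesh
#'
#' Displaces each control point along its radial deformation direction by the
#' corresponding entry of the local deformation state.
#'
#' @param mesh A `ds_mesh`.
#' @param x_l Numeric vector of signed radial displacements (mm), one per
#'   control point. The zero vector reproduces the mesh exactly.
#' @return The deformed `ds_mesh` (topology and directions unchanged).
#' @export
apply_local_deform <- function(mesh, x_l) {
  n <- nrow(mesh$points)
  if (length(x_l) != n)
    stop("length of 'x_l' (", length(x_l), ") must equal control point count (", n, ")")
  mesh$points <- mesh$points + as.numeric(x_l) * mesh$dirs
  mesh
}

# grid vertex index, column-major over rings
.grid_idx <- function(i, j, nr) (j - 1L) * nr + i

# One Doo-Sabin refinement of an (nr rings x nc columns) cylindrical quad
# grid, returned as the (2(nr-1) x 2nc) x (nr nc) linear refinement matrix.
# Per quad face the new point for a corner uses the standard Doo-Sabin
# valence-4 weights 9/16 (own), 3/16 (edge-adjacent), 1/16 (diagonal),
# i.e. alpha_0 = (n+5)/(4n), alpha_i = (3 + 2 cos(2 pi i / n))/(4n), n = 4.
# Boundary rows are handled by the faces that exist (open cylinder ends).
.ds_refine_matrix <- function(nr, nc) {
  nr2 <- 2L * (nr - 1L); nc2 <- 2L * nc
  S <- matrix(0, nr2 * nc2, nr * nc)
  w_own <- 9 / 16; w_adj <- 3 / 16; w_diag <- 1 / 16
  for (j in seq_len(nc)) {
    jp <- if (j == nc) 1L else j + 1L
    for (i in seq_len(nr - 1L)) {
      v00 <- .grid_idx(i, j, nr);  v10 <- .grid_idx(i + 1L, j, nr)
      v01 <- .grid_idx(i, jp, nr); v11 <- .grid_idx(i + 1L, jp, nr)
      # new vertices: rows 2i-1 / 2i, cols 2j-1 (corner col j) and 2j (corner col jp)
      n00 <- .grid_idx(2L * i - 1L, 2L * j - 1L, nr2)
      n10 <- .grid_idx(2L * i,      2L * j - 1L, nr2)
      n01 <- .grid_idx(2L * i - 1L, 2L * j,      nr2)
      n11 <- .grid_idx(2L * i,      2L * j,      nr2)
      S[n00, c(v00, v10, v01, v11)] <- c(w_own, w_adj, w_adj, w_diag)
      S[n10, c(v10, v00, v11, v01)] <- c(w_own, w_adj, w_adj, w_diag)
      S[n01, c(v01, v11, v00, v10)] <- c(w_own, w_adj, w_adj, w_diag)
      S[n11, c(v11, v01, v10, v00)] <- c(w_own, w_adj, w_adj, w_diag)
    }
  }
  S
}

# cache of composed refinement weight matrices, keyed by topology + levels
.ds_cache <- new.env(parent = emptyenv())

# Composed weights mapping control points -> refined grid after `levels`
# subdivisions. Returns list(W, nr, nc).
.ds_weights <- function(rings, ppr, levels) {
  key <- paste0("w", rings, "x", ppr, "l", levels)
  got <- .ds_cache[[key]]
  if (!is.null(got)) return(got)
  nr <- rings; nc <- ppr
  W <- diag(nr * nc)
  lv <- 0L
  while (lv < levels) {
    W <- .ds_refine_matrix(nr, nc) %*% W
    nr <- 2L * (nr - 1L); nc <- 2L * nc
    lv <- lv + 1L
  }
  out <- list(W = W, nr = nr, nc = nc)
  .ds_cache[[key]] <- out
  out
}

# quad faces of an (nr x nc) cylindrical grid (counter-clockwise seen from
# outside), as an nf x 4 index matrix
.grid_faces <- function(nr, nc) {
  nf <- (nr - 1L) * nc
  F <- matrix(0L, nf, 4L)
  k <- 1L
  for (j in seq_len(nc)) {
    jp <- if (j == nc) 1L else j + 1L
    for (i in seq_len(nr - 1L)) {
      F[k, ] <- c(.grid_idx(i, j, nr), .grid_idx(i, jp, nr),
                  .grid_idx(i + 1L, jp, nr), .grid_idx(i + 1L, j, nr))
      k <- k + 1L
    }
  }
  F
}

#' Doo-Sabin subdivision of the cylindrical control mesh
#'
#' Applies `levels` Doo-Sabin refinements. The scheme is linear, so the
#' refined vertices are returned together with the weight matrix `W` mapping
#' control points to refined vertices (`vertices == W %*% control_points`).
#'
#' @param mesh A `ds_mesh` (optionally already deformed).
#' @param levels Number of refinement levels (>= 0; 0 returns the control
#'   grid unchanged).
#' @return List with `vertices` (n x 3), `faces` (quad index matrix), `nr`,
#'   `nc` (refined grid dimensions) and `W` (weight matrix).
#' @export
ds_subdivide <- function(mesh, levels = 3L) {
  levels <- as.integer(levels)
  if (levels < 0L) stop("'levels' must be >= 0")
  w <- .ds_weights(mesh$rings, mesh$points_per_ring, levels)
  fkey <- paste0("f", w$nr, "x", w$nc)
  faces <- .ds_cache[[fkey]]
  if (is.null(faces)) {
    faces <- .grid_faces(w$nr, w$nc)
    .ds_cache[[fkey]] <- faces
  }
  list(vertices = w$W %*% mesh$points, faces = faces,
       nr = w$nr, nc = w$nc, W = w$W)
}

# Bilinear interpolation weights on the refined (nr x nc) grid at parameter
# (u in [0,1] axial, v in [0,1) angular, wrapped). Returns a sparse-style
# weight row as (indices, weights).
.bilinear_rows <- function(u, v, nr, nc) {
  fi <- 1 + u * (nr - 1)          # fractional ring coordinate
  fj <- 1 + (v %% 1) * nc         # fractional column coordinate, wraps
  i0 <- pmin(pmax(floor(fi), 1), nr - 1); ti <- fi - i0
  j0 <- floor(fj); tj <- fj - j0
  j0w <- ((j0 - 1L) %% nc) + 1L
  j1w <- (j0 %% nc) + 1L
  n <- length(u)
  idx <- cbind(.grid_idx(i0,      j0w, nr), .grid_idx(i0 + 1L, j0w, nr),
               .grid_idx(i0,      j1w, nr), .grid_idx(i0 + 1L, j1w, nr))
  wts <- cbind((1 - ti) * (1 - tj), ti * (1 - tj), (1 - ti) * tj, ti * tj)
  list(idx = idx, wts = wts, n = n)
}

# Dense sampling matrix (n_samples x n_control) combining bilinear patch
# interpolation on the refined grid with the composed subdivision weights.
.sample_matrix <- function(u, v, rings, ppr, levels) {
  w <- .ds_weights(rings, ppr, levels)
  br <- .bilinear_rows(u, v, w$nr, w$nc)
  A <- matrix(0, br$n, w$nr * w$nc)
  for (c in 1:4) A[cbind(seq_len(br$n), br$idx[, c])] <-
      A[cbind(seq_len(br$n), br$idx[, c])] + br$wts[, c]
  A %*% w$W
}

# Sampler with fixed parameterization: precomputes weight matrices for the
# sample points and for small parameter offsets (tangent estimation).
# Cached per (topology, levels, n_axial, n_angular).
.ds_sampler <- function(rings, ppr, levels, n_axial, n_angular) {
  key <- paste0("s", rings, "x", ppr, "l", levels, "a", n_axial, "g", n_angular)
  got <- .ds_cache[[key]]
  if (!is.null(got)) return(got)
  u1 <- (seq_len(n_axial) - 0.5) / n_axial
  v1 <- (seq_len(n_angular) - 1) / n_angular
  g <- expand.grid(u = u1, v = v1)     # axial fastest; fixed material points
  d <- 1e-3
  out <- list(
    S    = .sample_matrix(g$u,     g$v,     rings, ppr, levels),
    S_up = .sample_matrix(g$u + d, g$v,     rings, ppr, levels),
    S_um = .sample_matrix(g$u - d, g$v,     rings, ppr, levels),
    S_vp = .sample_matrix(g$u,     g$v + d, rings, ppr, levels),
    S_vm = .sample_matrix(g$u,     g$v - d, rings, ppr, levels),
    u = g$u, v = g$v, n_axial = n_axial, n_angular = n_angular)
  .ds_cache[[key]] <- out
  out
}

# radius of the undeformed limit surface at the model mid-plane z = 0
.ds_mid_radius <- function(mesh) {
  S <- .sample_matrix(0.5, 0, mesh$rings, mesh$points_per_ring, 3L)
  p <- as.numeric(S %*% mesh$points)
  sqrt(p[1]^2 + p[2]^2)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Sample the deformed model surface and annulus disc
#'
#' Evaluates `n_tube` points evenly distributed over the subdivision surface
#' (a fixed grid in angular/axial parameter space, so the same material
#' points are tracked whatever the deformation state) plus `n_disc` points on
#' the annulus disc boundary circle at the model mid-plane. Each sample
#' carries its model-frame position, outward unit normal, and the Jacobian of
#' position with respect to the local deformation states. The disc is rigid:
#' its samples have zero deformation Jacobian.
#'
#' @param mesh A `ds_mesh`.
#' @param x_l Local deformation state (defaults to zero).
#' @param n_tube Number of tube samples, as `n_angular x n_axial`
#'   (default 300 = 20 x 15). Must factor as `n_angular * n_axial`; supplied
#'   via `n_angular` and `n_axial` directly.
#' @param n_angular,n_axial Tube sampling grid (default 20 x 15 = 300 points).
#' @param n_disc Number of disc-edge samples (default 40).
#' @param levels Subdivision depth for surface evaluation (default 3; the
#'   sampled positions are then within ~0.01 mm of the limit surface).
#' @return List with `p_l` (n x 3 positions, mm), `n_l` (n x 3 unit outward
#'   normals), `S` (n x n_control deformation weight matrix; row i times the
#'   deformation directions gives J_l for sample i; zero rows for disc
#'   samples), `type` (`"tube"`/`"disc"`), and grid coordinates `gi`, `gj`
#'   used for neighbourhood-based outlier rejection.
#' @export
sample_surface <- function(mesh, x_l = NULL, n_angular = 20L, n_axial = 15L,
                           n_disc = 40L, levels = 3L) {
  if (n_angular < 1L || n_axial < 1L || n_disc < 1L) stop("sample counts must be positive")
  n_ctrl <- nrow(mesh$points)
  if (is.null(x_l)) x_l <- numeric(n_ctrl)
  if (length(x_l) != n_ctrl) stop("'x_l' length must equal control point count")
  P <- mesh$points + as.numeric(x_l) * mesh$dirs
  sm <- .ds_sampler(mesh$rings, mesh$points_per_ring, levels, n_axial, n_angular)
  pos <- sm$S %*% P
  tu <- sm$S_up %*% P - sm$S_um %*% P
  tv <- sm$S_vp %*% P - sm$S_vm %*% P
  nrm <- .unit_rows(.cross3(tu, tv))
  flip <- rowSums(nrm[, 1:2, drop = FALSE] * pos[, 1:2, drop = FALSE]) < 0
  nrm[flip, ] <- -nrm[flip, ]
  # annulus disc boundary: rigid circle in the z = 0 plane, radial normals
  ang <- 2 * pi * (seq_len(n_disc) - 1) / n_disc
  pd <- cbind(mesh$disc_radius * cos(ang), mesh$disc_radius * sin(ang), 0)
  nd <- cbind(cos(ang), sin(ang), 0)
  nt <- nrow(pos)
  list(p_l = rbind(pos, pd),
       n_l = rbind(nrm, nd),
       S = rbind(sm$S, matrix(0, n_disc, n_ctrl)),
       type = rep(c("tube", "disc"), c(nt, n_disc)),
       gi = c(rep(seq_len(n_axial), n_angular), rep(1L, n_disc)),
       gj = c(rep(seq_len(n_angular), each = n_axial), seq_len(n_disc)),
       n_angular = n_angular, n_axial = n_axial, n_disc = n_disc)
}
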