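# Annulus quantification: intersection of the deformed surface with the
# annulus disc plane, direct least-squares ellipse fit with geometric
# (Sampson) refinement, diameter/area/perimeter measures, and mid-systole
# selection.

# orthonormal in-plane basis for a unit plane normal
.plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(n[2] * a[3] - n[3] * a[2], n[3] * a[1] - n[1] * a[3], n[1] * a[2] - n[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3], n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

#' Intersect a triangulated surface with the annulus disc plane
#'
#' Computes the intersection polyline of a (quad-grid) surface mesh with a
#' plane, chains the crossing segments into closed loops, selects the loop
#' enclosing the disc centre, and returns its points ordered by angle around
#' the centre.
#'
#' @param vertices n x 3 matrix of mesh vertex positions (mm).
#' @param faces Quad index matrix (as returned by [ds_subdivide()]).
#' @param center Point on the plane (disc centre, mm).
#' @param normal Plane (disc) normal.
#' @return m x 3 matrix of ordered intersection points, or `NULL` when the
#'   plane misses the surface or no loop encloses the centre.
#' @export
intersect_annulus <- function(vertices, faces, center, normal) {
  b <- .plane_basis(normal)
  d <- as.numeric((vertices - matrix(center, nrow(vertices), 3, byrow = TRUE)) %*% b$n)
  tris <- rbind(faces[, c(1, 2, 3)], faces[, c(1, 3, 4)])
  dt <- matrix(d[tris], nrow(tris), 3)
  crossing <- which(pmin(dt[, 1], dt[, 2], dt[, 3]) < 0 &
                    pmax(dt[, 1], dt[, 2], dt[, 3]) >= 0)
  if (length(crossing) < 3) return(NULL)
  # intersection point on each crossing mesh edge, keyed by vertex pair
  seg_from <- character(0); seg_to <- character(0)
  pts <- list()
  edge_point <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    if (is.null(pts[[key]])) {
      t <- d[i] / (d[i] - d[j])
      pts[[key]] <<- vertices[i, ] + t * (vertices[j, ] - vertices[i, ])
    }
    key
  }
  for (f in crossing) {
    vv <- tris[f, ]; dd <- dt[f, ]
    keys <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      di <- dd[e[1]]; dj <- dd[e[2]]
      if ((di < 0) != (dj < 0)) keys <- c(keys, edge_point(vv[e[1]], vv[e[2]]))
    }
    if (length(keys) == 2) { seg_from <- c(seg_from, keys[1]); seg_to <- c(seg_to, keys[2]) }
  }
  if (length(seg_from) < 3) return(NULL)
  # chain segments into loops via shared edge keys
  used <- rep(FALSE, length(seg_from))
  loops <- list()
  repeat {
    s <- which(!used)[1]
    if (is.na(s)) break
    loop <- c(seg_from[s], seg_to[s]); used[s] <- TRUE
    repeat {
      tail_key <- loop[length(loop)]
      nxt <- which(!used & (seg_from == tail_key | seg_to == tail_key))[1]
      if (is.na(nxt)) break
      used[nxt] <- TRUE
      loop <- c(loop, if (seg_from[nxt] == tail_key) seg_to[nxt] else seg_from[nxt])
    }
    if (loop[1] == loop[length(loop)]) loop <- loop[-length(loop)]
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  if (length(loops) == 0) return(NULL)
  to_xy <- function(keys) {
    P <- do.call(rbind, pts[keys])
    rel <- P - matrix(center, nrow(P), 3, byrow = TRUE)
    cbind(rel %*% b$e1, rel %*% b$e2)
  }
  encloses <- function(keys) {
    xy <- to_xy(keys)
    ang <- atan2(xy[, 2], xy[, 1])
    w <- sum(((diff(c(ang, ang[1])) + pi) %% (2 * pi)) - pi)
    abs(w) > pi  # winding number around the centre
  }
  keep <- NULL
  for (lp in loops) if (encloses(lp)) { keep <- lp; break }
  if (is.null(keep)) return(NULL)
  P <- do.call(rbind, pts[keep])
  xy <- to_xy(keep)
  P[order(atan2(xy[, 2], xy[, 1])), , drop = FALSE]
}

#' Direct least-squares ellipse fit with Sampson refinement
#'
#' Fits an ellipse to 2D points: a direct algebraic conic fit constrained to
#' ellipses (Fitzgibbon-style, in the numerically stable partitioned form)
#' initializes a Gauss-style refinement minimizing the Sampson
#' (gradient-normalized algebraic) distance, so the result is insensitive to
#' the choice of algebraic normalization.
#'
#' @param xy m x 2 matrix of points (m >= 5).
#' @param refine Run the Sampson refinement (default `TRUE`).
#' @return List with `center` (length 2), semi-axes `a >= b`, and
#'   orientation `phi` (radians, major axis vs x); or `NULL` on degenerate
#'   input.
#' @export
fit_ellipse <- function(xy, refine = TRUE) {
  if (is.null(dim(xy)) || nrow(xy) < 5) return(NULL)
  x <- xy[, 1]; y <- xy[, 2]
  mx <- mean(x); my <- mean(y); sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T2)) return(NULL)
  M <- S1 + S2 %*% T2
  # constraint 4ac - b^2 = 1: premultiply by inv(C1)
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0) return(NULL)
  a1 <- V[, k[1]]
  par6 <- c(a1, T2 %*% a1)   # A B C D E F in scaled coords
  geo <- .conic_to_geo(par6)
  if (is.null(geo)) return(NULL)
  # undo scaling
  geo$center <- geo$center * sc + c(mx, my)
  geo$a <- geo$a * sc; geo$b <- geo$b * sc
  if (refine) geo <- .sampson_refine(xy, geo)
  geo
}

.conic_to_geo <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F <- p[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  mu <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  e <- eigen(Q, symmetric = TRUE)
  lam <- e$values  # decreasing
  if (any(-mu / lam <= 0)) return(NULL)
  ax <- sqrt(-mu / lam)   # lam sorted decreasing -> ax increasing
  a <- max(ax); b <- min(ax)
  vecmax <- e$vectors[, which.min(lam)]  # minor eigenvalue -> major axis dir
  phi <- atan2(vecmax[2], vecmax[1])
  list(center = c(cx, cy), a = a, b = b, phi = phi %% pi)
}

.sampson_refine <- function(xy, geo) {
  obj <- function(p) {
    cx <- p[1]; cy <- p[2]; a <- abs(p[3]); b <- abs(p[4]); phi <- p[5]
    if (a < 1e-9 || b < 1e-9) return(1e12)
    co <- cos(phi); si <- sin(phi)
    xr <- (xy[, 1] - cx) * co + (xy[, 2] - cy) * si
    yr <- -(xy[, 1] - cx) * si + (xy[, 2] - cy) * co
    Qv <- (xr / a)^2 + (yr / b)^2 - 1
    g2 <- (2 * xr / a^2)^2 + (2 * yr / b^2)^2
    sum(Qv^2 / pmax(g2, 1e-12))
  }
  p0 <- c(geo$center, geo$a, geo$b, geo$phi)
  fit <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                               control = list(maxit = 200, reltol = 1e-12)),
                  error = function(e) NULL)
  if (is.null(fit)) return(geo)
  p <- fit$par
  a <- abs(p[3]); b <- abs(p[4]); phi <- p[5]
  if (b > a) { tmp <- a; a <- b; b <- tmp; phi <- phi + pi / 2 }
  list(center = p[1:2], a = a, b = b, phi = phi %% pi)
}

#' Perimeter of an ellipse
#'
#' Ramanujan's second approximation (relative error below 1e-6 for the
#' aspect ratios arising here), with adaptive quadrature of the arc-length
#' integral as an alternative.
#'
#' @param a,b Semi-axes.
#' @param method `"ramanujan"` (default) or `"quadrature"`.
#' @return Perimeter.
#' @export
ellipse_perimeter <- function(a, b, method = c("ramanujan", "quadrature")) {
  method <- match.arg(method)
  if (method == "ramanujan") {
    h <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  } else {
    e2 <- 1 - (min(a, b) / max(a, b))^2
    A <- max(a, b)
    4 * A * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2), 0, pi / 2,
                             rel.tol = 1e-10)$value
  }
}

#' Diameter, area and perimeter measures of a fitted annulus ellipse
#'
#' @param ellipse Result of [fit_ellipse()] (`a`, `b` used).
#' @return List with `major_d`, `minor_d`, `area`, `perimeter`,
#'   `area_derived_d` (diameter of the equal-area circle) and
#'   `perimeter_derived_d` (diameter of the equal-perimeter circle; the
#'   method's main output diameter since it varies least over the cycle).
#' @export
ellipse_measures <- function(ellipse) {
  a <- ellipse$a; b <- ellipse$b
  per <- ellipse_perimeter(a, b)
  list(major_d = 2 * a, minor_d = 2 * b, area = pi * a * b, perimeter = per,
       area_derived_d = 2 * sqrt(a * b), perimeter_derived_d = per / pi)
}

#' Select the mid-systolic frame
#'
#' Mid systole is defined as the frame with maximum detected annulus area
#' (earliest frame on ties).
#'
#' @param areas Per-frame annulus areas (`NA` for failed frames).
#' @return Frame index, or `NA` if no frame is valid.
#' @export
select_mid_systole <- function(areas) {
  if (all(is.na(areas))) return(NA_integer_)
  which.max(replace(areas, is.na(areas), -Inf))
}
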