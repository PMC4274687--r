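# Annulus quantification: plane sections of cylinders, ellipse fitting with
# Monte-Carlo and quadrature oracles, measures, mid-systole selection.

# dense triangulated cylinder for section tests
cyl_mesh <- function(R = 10, halflen = 15, nz = 40, na = 64) {
  z <- seq(-halflen, halflen, length.out = nz)
  a <- 2 * pi * (seq_len(na) - 1) / na
  g <- expand.grid(z = z, a = a)
  verts <- cbind(R * cos(g$a), R * sin(g$a), g$z)
  idx <- function(i, j) (j - 1L) * nz + i
  faces <- matrix(0L, (nz - 1) * na, 4)
  k <- 1L
  for (j in seq_len(na)) {
    jp <- if (j == na) 1L else j + 1L
    for (i in seq_len(nz - 1)) {
      faces[k, ] <- c(idx(i, j), idx(i, jp), idx(i + 1, jp), idx(i + 1, j))
      k <- k + 1L
    }
  }
  list(vertices = verts, faces = faces)
}

test_that("perpendicular and oblique cylinder sections give circle and ellipse", {
  cm <- cyl_mesh(R = 10)
  # perpendicular plane: circle of radius 10
  pts <- intersect_annulus(cm$vertices, cm$faces, c(0, 0, 0), c(0, 0, 1))
  expect_false(is.null(pts))
  r <- sqrt(rowSums(pts[, 1:2]^2))
  expect_lt(max(abs(r - 10)), 0.02)
  expect_lt(max(abs(pts[, 3])), 1e-9)
  # oblique plane at angle alpha: semi-axes R and R / cos(alpha)
  alpha <- 25 * pi / 180
  nrm <- c(sin(alpha), 0, cos(alpha))
  pts2 <- intersect_annulus(cm$vertices, cm$faces, c(0, 0, 0), nrm)
  b <- annulusEKF:::.plane_basis(nrm)
  xy <- cbind(pts2 %*% b$e1, pts2 %*% b$e2)
  el <- fit_ellipse(xy)
  expect_equal(el$b, 10, tolerance = 1e-2)
  expect_equal(el$a, 10 / cos(alpha), tolerance = 1e-2)
  # plane entirely outside the tube: failure signal
  expect_null(intersect_annulus(cm$vertices, cm$faces, c(0, 0, 100), c(0, 0, 1)))
})

test_that("ellipse fitting recovers exact circles and ellipses", {
  a <- 2 * pi * (seq_len(40) - 1) / 40
  circ <- cbind(10 * cos(a), 10 * sin(a))
  el <- fit_ellipse(circ)
  expect_equal(el$a, 10, tolerance = 1e-9)
  expect_equal(el$b, 10, tolerance = 1e-9)
  expect_equal(el$center, c(0, 0), tolerance = 1e-9)
  ell <- cbind(3 + 15 * cos(a) * cos(0.4) - 10 * sin(a) * sin(0.4),
               -2 + 15 * cos(a) * sin(0.4) + 10 * sin(a) * cos(0.4))
  el2 <- fit_ellipse(ell)
  expect_equal(el2$a, 15, tolerance = 1e-8)
  expect_equal(el2$b, 10, tolerance = 1e-8)
  expect_equal(el2$center, c(3, -2), tolerance = 1e-8)
  expect_equal(el2$phi, 0.4, tolerance = 1e-6)
  expect_null(fit_ellipse(cbind(1:10, 2 * (1:10))))  # collinear
  expect_null(fit_ellipse(circ[1:4, ]))              # too few points
})

test_that("noisy ellipse fits are unbiased against a nonlinear LS oracle", {
  set.seed(17)
  a <- 2 * pi * (seq_len(40) - 1) / 40
  reps <- 120
  ahat <- numeric(reps); ahat_o <- numeric(reps)
  for (r in seq_len(reps)) {
    xy <- cbind(15 * cos(a), 10 * sin(a)) + matrix(rnorm(80, 0, 0.2), 40, 2)
    el <- fit_ellipse(xy)
    ahat[r] <- el$a
    # independent oracle: direct nonlinear least squares on radial distances
    obj <- function(p) {
      xr <- (xy[, 1] - p[1]); yr <- (xy[, 2] - p[2])
      sum((sqrt((xr / p[3])^2 + (yr / p[4])^2) - 1)^2)
    }
    ahat_o[r] <- stats::optim(c(0, 0, 15, 10), obj)$par[3]
  }
  expect_lt(abs(mean(ahat) - 15), 0.1)
  expect_lt(abs(mean(ahat) - mean(ahat_o)), 0.1)
})

test_that("ellipse measures match closed forms and the quadrature oracle", {
  m <- ellipse_measures(list(a = 3, b = 3))
  expect_equal(m$area, pi * 9)
  expect_equal(m$perimeter, 2 * pi * 3, tolerance = 1e-9)
  expect_equal(m$area_derived_d, 6)
  expect_equal(m$perimeter_derived_d, 6, tolerance = 1e-9)
  m2 <- ellipse_measures(list(a = 2, b = 1))
  expect_equal(m2$area, 2 * pi)
  expect_equal(m2$area_derived_d, 2 * sqrt(2))
  # Ramanujan II against adaptive quadrature of the arc-length integral
  for (ab in list(c(15, 10), c(12, 11.5), c(20, 8))) {
    expect_equal(ellipse_perimeter(ab[1], ab[2]),
                 ellipse_perimeter(ab[1], ab[2], method = "quadrature"),
                 tolerance = 1e-6)
  }
})

test_that("derived diameters obey the power-mean and isoperimetric relations", {
  set.seed(33)
  for (i in 1:50) {
    ab <- sort(runif(2, 5, 20), decreasing = TRUE)
    m <- ellipse_measures(list(a = ab[1], b = ab[2]))
    expect_lte(m$minor_d, m$area_derived_d + 1e-9)
    expect_lte(m$area_derived_d, m$major_d + 1e-9)
    # equal-perimeter circle is at least as large as the equal-area circle
    expect_gte(m$perimeter_derived_d, m$area_derived_d - 1e-9)
  }
  mc <- ellipse_measures(list(a = 7, b = 7))
  expect_equal(mc$perimeter_derived_d, mc$area_derived_d, tolerance = 1e-9)
})

test_that("measures are invariant under rigid motion of the section points", {
  cm <- cyl_mesh(R = 8)
  alpha <- 0.3
  nrm <- c(sin(alpha), 0, cos(alpha))
  pts <- intersect_annulus(cm$vertices, cm$faces, c(0, 0, 0), nrm)
  R <- annulusEKF:::.axis_angle(c(1, 2, 0.5) / sqrt(5.25), 0.9)
  shift <- c(4, -7, 2)
  pts2 <- pts %*% t(R) + matrix(shift, nrow(pts), 3, byrow = TRUE)
  fitxy <- function(p, n) {
    b <- annulusEKF:::.plane_basis(n)
    ctr <- colMeans(p)
    rel <- p - matrix(ctr, nrow(p), 3, byrow = TRUE)
    fit_ellipse(cbind(rel %*% b$e1, rel %*% b$e2))
  }
  e1 <- fitxy(pts, nrm)
  e2 <- fitxy(pts2, as.numeric(R %*% nrm))
  expect_equal(ellipse_measures(e1)$perimeter, ellipse_measures(e2)$perimeter,
               tolerance = 1e-6)
  expect_equal(e1$a, e2$a, tolerance = 1e-6)
})

test_that("mid-systole selection takes the earliest maximum-area frame", {
  expect_equal(select_mid_systole(c(3, 5, 4)), 2L)
  expect_equal(select_mid_systole(c(5, 5, 4)), 1L)
  expect_equal(select_mid_systole(c(NA, 2, NA)), 2L)
  expect_true(is.na(select_mid_systole(c(NA_real_, NA_real_))))
})
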