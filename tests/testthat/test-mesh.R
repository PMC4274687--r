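# Subdivision-surface core: construction invariants, local deformation,
# Doo-Sabin refinement combinatorics and linearity, sampling Jacobians.

test_that("default mesh construction matches the cylindrical control-net contract", {
  m <- ds_mesh(20, 40)
  expect_equal(nrow(m$points), 30)
  expect_equal(m$rings, 5L)
  expect_equal(m$points_per_ring, 6L)
  # ring radii 10 mm, z levels -20..20 in steps of 10
  r <- sqrt(m$points[, 1]^2 + m$points[, 2]^2)
  expect_equal(r, rep(10, 30), tolerance = 1e-12)
  expect_setequal(round(unique(m$points[, 3]), 9), c(-20, -10, 0, 10, 20))
  # deformation directions: unit norm, zero z-component
  expect_equal(rowSums(m$dirs^2), rep(1, 30), tolerance = 1e-12)
  expect_equal(m$dirs[, 3], rep(0, 30))
  expect_error(ds_mesh(-1, 40), "positive")
  expect_error(ds_mesh(20, 0), "positive")
})

test_that("local deformation is the stated radial displacement with exact inverse", {
  m <- ds_mesh(24, 40)
  expect_equal(apply_local_deform(m, numeric(30)), m)
  # uniform +c on all rings puts control points at radius R + c
  md <- apply_local_deform(m, rep(2.5, 30))
  expect_equal(sqrt(rowSums(md$points[, 1:2]^2)), rep(14.5, 30), tolerance = 1e-12)
  # random deformation followed by its negation restores the mesh
  set.seed(11)
  xl <- rnorm(30)
  m2 <- apply_local_deform(apply_local_deform(m, xl), -xl)
  expect_equal(m2$points, m$points, tolerance = 1e-14)
  expect_error(apply_local_deform(m, numeric(10)), "control point count")
})

test_that("Doo-Sabin refinement has dual combinatorics and affine invariance", {
  m <- ds_mesh(20, 30)
  s0 <- ds_subdivide(m, 0)
  expect_equal(s0$vertices, m$points)
  s1 <- ds_subdivide(m, 1)
  # one new vertex per (face, vertex) pair: 24 quads x 4
  expect_equal(nrow(s1$vertices), 4 * (m$rings - 1) * m$points_per_ring)
  expect_equal(s1$nr, 8L); expect_equal(s1$nc, 12L)
  # rows of the weight matrix are convex combinations
  expect_equal(rowSums(s1$W), rep(1, nrow(s1$W)), tolerance = 1e-12)
  expect_true(all(s1$W >= 0))
  # affine invariance: transform-then-subdivide == subdivide-then-transform
  set.seed(3)
  A <- matrix(rnorm(9), 3, 3); b <- rnorm(3)
  m2 <- m
  m2$points <- m$points %*% t(A) + matrix(b, 30, 3, byrow = TRUE)
  lhs <- ds_subdivide(m2, 2)$vertices
  rhs <- ds_subdivide(m, 2)$vertices %*% t(A) + matrix(b, nrow(lhs), 3, byrow = TRUE)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("surface samples are linear in deformations with correct Jacobians", {
  m <- ds_mesh(22, 36)
  smp <- sample_surface(m)
  expect_equal(nrow(smp$p_l), 300 + 40)
  expect_equal(sum(smp$type == "tube"), 300)
  # undeformed cylinder: outward radial normals, zero z-component
  tube <- smp$type == "tube"
  expect_lt(max(abs(smp$n_l[tube, 3])), 1e-10)
  expect_true(all(rowSums(smp$n_l[tube, 1:2] * smp$p_l[tube, 1:2]) > 0))
  expect_equal(rowSums(smp$n_l^2), rep(1, nrow(smp$n_l)), tolerance = 1e-12)
  # disc samples carry no deformation weights
  expect_equal(max(abs(smp$S[smp$type == "disc", ])), 0)
  # central-difference oracle for every deformation column
  set.seed(7)
  xl <- rnorm(30, 0, 0.5)
  eps <- 1e-4
  s0 <- sample_surface(m, xl)
  for (j in c(1, 8, 15, 23, 30)) {
    xp <- xl; xp[j] <- xp[j] + eps
    xm <- xl; xm[j] <- xm[j] - eps
    fd <- (sample_surface(m, xp)$p_l - sample_surface(m, xm)$p_l) / (2 * eps)
    an <- s0$S[, j] %o% m$dirs[j, ]
    expect_lt(max(abs(fd - an)), 1e-6)
  }
})

test_that("sampling is linear (superposition) and deterministic", {
  m <- ds_mesh(25, 40)
  set.seed(5)
  x1 <- rnorm(30); x2 <- rnorm(30)
  a <- 0.3; b <- -1.7
  p_lin <- sample_surface(m, a * x1 + b * x2)$p_l
  p_sup <- a * sample_surface(m, x1)$p_l + b * sample_surface(m, x2)$p_l +
    (1 - a - b) * sample_surface(m, numeric(30))$p_l
  expect_equal(p_lin, p_sup, tolerance = 1e-10)
  expect_identical(sample_surface(m, x1), sample_surface(m, x1))
})

test_that("uniform inflation moves the limit surface outward by the ring shrink factor", {
  m <- ds_mesh(20, 40)
  tube <- function(s) s$type == "tube"
  s0 <- sample_surface(m)
  s1 <- sample_surface(m, rep(1, 30))
  r0 <- sqrt(rowSums(s0$p_l[tube(s0), 1:2]^2))
  r1 <- sqrt(rowSums(s1$p_l[tube(s1), 1:2]^2))
  dr <- r1 - r0
  expect_true(all(dr > 0))
  # linear scheme: the radial increment is the same factor everywhere, equal
  # to the Doo-Sabin contraction of a hexagonal ring (~0.87), not exactly 1
  expect_lt(diff(range(dr)), 0.02)
  expect_gt(mean(dr), 0.8)
  expect_lt(mean(dr), 1)
})

test_that("root template scales the sinus ring and keeps the annulus ring nominal", {
  sc <- root_template_scale()
  m <- ds_mesh(25, 40, ring_scale = sc)
  r <- sqrt(rowSums(m$points[, 1:2]^2))
  z <- m$points[, 3]
  expect_true(all(abs(r[z == 0] - 12.5) < 1e-9))
  expect_true(all(abs(r[z == 10] - 12.5 * 1.3) < 1e-9))
})
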