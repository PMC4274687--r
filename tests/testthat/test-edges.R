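# Edge detection: profile extraction on analytic fields, step/peak fitting
# with a Monte-Carlo oracle, outlier rejection, variance normalization.

test_that("profiles are sampled symmetrically and reproduce analytic fields", {
  cfg <- edge_config(search_mm = 10, n_samples = 21L)
  vol <- halfspace_volume(x0 = 0)
  p <- matrix(c(0, 0, 0), 1)
  n <- matrix(c(1, 0, 0), 1)
  pr <- extract_profiles(vol, p, n, cfg)
  expect_equal(pr$offsets, seq(-10, 10, length.out = 21))
  expect_true(pr$usable[1])
  # step field: intensity 0 below x0, 100 above (trilinear ramp within a voxel)
  expect_equal(pr$intensities[1, pr$offsets <= -1], rep(0, sum(pr$offsets <= -1)))
  expect_equal(pr$intensities[1, pr$offsets >= 1], rep(100, sum(pr$offsets >= 1)))
  # constant volume gives a constant profile
  volc <- volume3d(array(7, c(9, 9, 9)), spacing = c(1, 1, 1), origin = c(-4, -4, -4))
  prc <- extract_profiles(volc, matrix(0, 1, 3), n, edge_config(search_mm = 3, n_samples = 7L))
  expect_equal(as.numeric(prc$intensities), rep(7, 7))
})

test_that("profiles leaving the volume are flagged unusable", {
  vol <- halfspace_volume()
  cfg <- edge_config(search_mm = 100, n_samples = 41L)
  pr <- extract_profiles(vol, matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1), cfg)
  expect_false(pr$usable[1])
})

test_that("noiseless steps are localized to within half a sample step", {
  cfg <- edge_config(search_mm = 14, n_samples = 29L, fit_model = "step")
  off <- seq(-14, 14, length.out = 29)
  for (d in c(-11, -4.7, 0.3, 2, 9.9)) {
    X <- matrix(100 * (off > d), 1)
    ed <- fit_edges(make_profiles(X, 14), cfg)
    expect_true(ed$ok[1])
    expect_lt(abs(ed$v[1] - d), 0.5 + 1e-9)  # step is 1 mm here
    expect_equal(ed$residual[1], 0, tolerance = 1e-9)
    expect_equal(ed$step_height[1], 100, tolerance = 1e-9)
  }
  # flat profile yields no edge
  edf <- fit_edges(make_profiles(matrix(5, 1, 29), 14), cfg)
  expect_false(edf$ok[1])
})

test_that("peak templates localize a bright wall and auto-selection prefers them", {
  cfg <- edge_config(search_mm = 7, n_samples = 15L, fit_model = "auto")
  off <- seq(-7, 7, length.out = 15)
  # lumen 20 | wall 200 (between 1 and 4 mm) | background 60
  X <- matrix(ifelse(off > 1 & off <= 4, 200, ifelse(off > 4, 60, 20)), 1)
  ed <- fit_edges(make_profiles(X, 7), cfg)
  expect_true(ed$ok[1])
  expect_equal(ed$model[1], "peak")
  expect_equal(ed$v[1], 2.5, tolerance = 0.51)  # centre of the bright band
  expect_equal(ed$residual[1], 0, tolerance = 1e-9)
})

test_that("noisy step detection is unbiased (Monte-Carlo oracle)", {
  cfg <- edge_config(search_mm = 14, n_samples = 29L, fit_model = "step")
  off <- seq(-14, 14, length.out = 29)
  set.seed(42)
  reps <- 200
  vs <- numeric(reps)
  resid <- numeric(reps)
  noise_ss <- numeric(reps)
  for (r in seq_len(reps)) {
    noise <- rnorm(29, 0, 5)
    X <- matrix(100 * (off > -3.5) + noise, 1)
    ed <- fit_edges(make_profiles(X, 14), cfg)
    vs[r] <- ed$v[1]
    resid[r] <- ed$residual[1]
    noise_ss[r] <- sum(noise^2)
  }
  expect_lt(abs(mean(vs) - (-3.5)), 0.2)
  # the fit explains the step, leaving roughly the noise energy
  expect_lt(abs(mean(resid) / mean(noise_ss) - 1), 0.15)
})

test_that("outlier rejection drops isolated deviants and is idempotent", {
  # 12 edges on a ring: neighbour structure from a 1 x 12 disc-like grid
  smp <- list(n_axial = 1L, n_angular = 1L, n_disc = 12L)
  nb <- annulusEKF:::.grid_neighbors_build(list(n_axial = 1L, n_angular = 1L, n_disc = 12L))
  nb <- nb[-1]  # drop the single tube sample entry
  nb <- lapply(nb, function(x) x - 1L)
  cfg <- edge_config(neighbor_max_delta_mm = 3, min_step_height = 10)
  ed <- data.frame(v = rep(0.2, 12), residual = 1, step_height = 50, ok = TRUE)
  out <- reject_outliers(ed, nb, cfg)
  expect_true(all(out$ok))
  # one deviant among flat neighbours is rejected
  ed$v[5] <- 10
  out <- reject_outliers(ed, nb, cfg)
  expect_false(out$ok[5])
  expect_equal(sum(out$ok), 11)
  # low amplitude is rejected regardless of agreement
  ed2 <- ed; ed2$v <- 0; ed2$step_height[3] <- 1
  out2 <- reject_outliers(ed2, nb, cfg)
  expect_false(out2$ok[3])
  # idempotence: re-running on its own output changes nothing
  set.seed(13)
  ed3 <- data.frame(v = rnorm(12, 0, 2), residual = 1,
                    step_height = runif(12, 0, 100), ok = runif(12) > 0.3)
  o1 <- reject_outliers(ed3, nb, cfg)
  o2 <- reject_outliers(o1, nb, cfg)
  expect_identical(o1$ok, o2$ok)
  expect_true(all(o1$ok <= ed3$ok))  # output is a subset
})

test_that("raising the amplitude threshold never grows the accepted set", {
  set.seed(31)
  nb <- annulusEKF:::.grid_neighbors_build(list(n_axial = 3L, n_angular = 5L, n_disc = 4L))
  ed <- data.frame(v = rnorm(19, 0, 2), residual = 1,
                   step_height = runif(19, 0, 100), ok = TRUE)
  prev <- rep(TRUE, 19)
  for (h in c(0, 20, 40, 60, 80, 101)) {
    cfg <- edge_config(min_step_height = h, neighbor_max_delta_mm = 1e6)
    ok <- reject_outliers(ed, nb, cfg)$ok
    expect_true(all(ok <= prev))
    prev <- ok
  }
  expect_false(any(prev))  # threshold above all amplitudes rejects everything
})

test_that("variance normalization scales residuals to sum exactly to r_edge", {
  expect_equal(normalize_variances(c(1, 3), 8), c(2, 6), tolerance = 1e-4)
  # all-zero residuals share r_edge uniformly through the epsilon guard
  expect_equal(normalize_variances(rep(0, 4), 1), rep(0.25, 4))
  set.seed(2)
  for (i in 1:20) {
    r <- rexp(sample(1:50, 1))
    out <- normalize_variances(r, 7.5)
    expect_equal(sum(out), 7.5, tolerance = 1e-12)
    expect_true(all(out > 0))
  }
  expect_length(normalize_variances(numeric(0), 1), 0)
})

test_that("total edge information scales as 1/r_edge", {
  # doubling r_edge halves the information sum (and so the update magnitude)
  set.seed(77)
  H <- matrix(rnorm(60), 20, 3)
  resid <- rexp(20)
  r1 <- normalize_variances(resid, 1)
  r2 <- normalize_variances(resid, 2)
  I1 <- crossprod(H / sqrt(r1))
  I2 <- crossprod(H / sqrt(r2))
  expect_equal(I1, 2 * I2, tolerance = 1e-10)
})
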