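# Kalman engine: prediction closed forms, information-form update against
# covariance-form and sequential-scalar oracles, assimilation identities.

test_that("prediction follows the regularized closed forms", {
  # A = I keeps the state, P grows by Q0
  p1 <- kf_predict(c(1, 2), diag(2), c(1, 1), c(9, 9), diag(0.5, 2))
  expect_equal(p1$x, c(1, 2))
  expect_equal(p1$P, diag(1.5, 2))
  # A = 0 resets to the regularization state with covariance Q0
  p0 <- kf_predict(c(1, 2), diag(2), c(0, 0), c(9, 9), diag(0.5, 2))
  expect_equal(p0$x, c(9, 9))
  expect_equal(p0$P, diag(0.5, 2))
  # scalar: a = 0.5, x = 2, x0 = 0 -> 1; P: 0.25 * 4 + 1 = 2
  ps <- kf_predict(2, matrix(4), 0.5, 0, matrix(1))
  expect_equal(ps$x, 1)
  expect_equal(ps$P, matrix(2))
  expect_error(kf_predict(1, matrix(1), 1.5, 0, matrix(1)), "\\[0, 1\\]")
})

test_that("scalar update matches hand computation and empty update is identity", {
  u <- kf_update(0, matrix(1), matrix(1, 1, 1), 1, 1)
  expect_equal(u$x, 0.5)
  expect_equal(u$P, matrix(0.5), tolerance = 1e-12)
  u0 <- kf_update(c(1, 2), diag(2), matrix(0, 0, 2), numeric(0), numeric(0))
  expect_equal(u0$x, c(1, 2))
  expect_equal(u0$P, diag(2), tolerance = 1e-12)
})

test_that("information update equals covariance-form and sequential oracles", {
  set.seed(123)
  for (case in 1:100) {
    d <- sample(c(2, 5, 9, 17, 37), 1)
    nmeas <- sample(c(1, 3, 20, 120, 300), 1)
    L <- matrix(rnorm(d * d), d)
    P <- crossprod(L) + diag(0.5, d)
    x <- rnorm(d)
    H <- matrix(rnorm(nmeas * d), nmeas, d)
    v <- rnorm(nmeas)
    r <- rexp(nmeas) + 0.05
    got <- kf_update(x, P, H, v, r)
    # covariance-form oracle on the stacked measurement; agreement measured
    # in the max norm relative to the matrix/vector scale
    K <- P %*% t(H) %*% solve(H %*% P %*% t(H) + diag(r, nmeas))
    x_cov <- x + as.numeric(K %*% v)
    # Joseph-stabilized covariance (the plain (I - KH)P form loses digits
    # under strong measurement sets and would dominate the comparison error)
    IKH <- diag(d) - K %*% H
    P_cov <- IKH %*% P %*% t(IKH) + K %*% diag(r, nmeas) %*% t(K)
    relmax <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-12)
    expect_lt(relmax(got$x, x_cov), 1e-8)
    expect_lt(relmax(got$P, (P_cov + t(P_cov)) / 2), 1e-8)
    # sequential scalar oracle (independent scalar measurements commute)
    if (case <= 20) {
      xs <- x; Ps <- P
      for (i in seq_len(nmeas)) {
        h <- H[i, ]
        S <- as.numeric(t(h) %*% Ps %*% h) + r[i]
        Ki <- (Ps %*% h) / S
        # v_i are innovations against the original prediction x, so the
        # absolute scalar measurement is z_i = v_i + h' x
        xs <- xs + as.numeric(Ki) * ((v[i] + sum(h * x)) - sum(h * xs))
        IKh <- diag(d) - Ki %*% t(h)
        Ps <- IKh %*% Ps %*% t(IKh) + r[i] * Ki %*% t(Ki)
      }
      expect_lt(relmax(got$x, xs), 1e-8)
      expect_lt(relmax(got$P, (Ps + t(Ps)) / 2), 1e-8)
    }
  }
})

test_that("measurements only ever increase precision and keep P symmetric", {
  set.seed(5)
  d <- 9
  L <- matrix(rnorm(d * d), d)
  P <- crossprod(L) + diag(0.1, d)
  x <- rnorm(d)
  for (i in 1:20) {
    H <- matrix(rnorm(d), 1, d)
    up <- kf_update(x, P, H, rnorm(1), rexp(1) + 0.1)
    expect_true(all(diag(up$P) <= diag(P) + 1e-12))
    expect_lt(max(abs(up$P - t(up$P))), 1e-10)
    x <- up$x; P <- up$P
  }
})

test_that("assimilation fuses by precision and is symmetric in its arguments", {
  # identical estimates: state kept, covariance halved
  set.seed(9)
  L <- matrix(rnorm(16), 4)
  P <- crossprod(L) + diag(0.2, 4)
  x <- rnorm(4)
  a <- kf_assimilate(x, P, x, P)
  expect_equal(a$x, x, tolerance = 1e-10)
  expect_equal(a$P, P / 2, tolerance = 1e-8)
  # scalar equal-weight average
  s <- kf_assimilate(0, matrix(1), 2, matrix(1))
  expect_equal(s$x, 1)
  expect_equal(s$P, matrix(0.5), tolerance = 1e-10)
  # a hopeless backward estimate contributes nothing
  w <- kf_assimilate(0, matrix(1), 10, matrix(1e6))
  expect_lt(abs(w$x), 0.01)
  # symmetry
  xf <- rnorm(4); xb <- rnorm(4)
  Lb <- matrix(rnorm(16), 4)
  Pb <- crossprod(Lb) + diag(0.3, 4)
  a1 <- kf_assimilate(xf, P, xb, Pb)
  a2 <- kf_assimilate(xb, Pb, xf, P)
  expect_equal(a1$x, a2$x, tolerance = 1e-9)
  expect_equal(a1$P, a2$P, tolerance = 1e-9)
})
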