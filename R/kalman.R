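# Extended Kalman filter core in information form: regularized prediction,
# measurement update accumulating scalar edge measurements into an
# information matrix/vector (one dim(x)-sized solve, never a matrix the size
# of the measurement set), and precision-weighted forward/backward fusion.

# symmetrize and enforce an eigenvalue floor so covariances stay SPD
.spd_floor <- function(P, floor = 1e-10) {
  P <- (P + t(P)) / 2
  e <- eigen(P, symmetric = TRUE)
  if (e$values[length(e$values)] < floor) {
    v <- pmax(e$values, floor)
    P <- e$vectors %*% (v * t(e$vectors))
    P <- (P + t(P)) / 2
  }
  P
}

# SPD solve with diagonal regularization fallback
.spd_solve <- function(A, B = diag(nrow(A))) {
  ch <- tryCatch(chol((A + t(A)) / 2), error = function(e) NULL)
  if (is.null(ch)) {
    reg <- max(abs(diag(A)), 1) * 1e-10
    ch <- chol((A + t(A)) / 2 + reg * diag(nrow(A)))
  }
  chol2inv(ch) %*% B
}

#' Kalman prediction with state regularization
#'
#' Predicts the next state as a convex combination of the previous estimate
#' and a regularization state, `x_pred = A x + (I - A) x0`, with covariance
#' `P_pred = A P A' + Q0`. `A` is diagonal with entries in `[0, 1]` chosen
#' per state class (translation, scale, rotation, deformation); it acts as a
#' temporal regularizer, and `Q0` sets how much the filter trusts the
#' prediction relative to the edge measurements.
#'
#' @param x State estimate vector.
#' @param P State covariance matrix.
#' @param A Diagonal of the regularization matrix (vector, entries in
#'   `[0, 1]`).
#' @param x0 Regularization state vector.
#' @param Q0 Process noise covariance (matrix, or vector of diagonal
#'   entries).
#' @return List with predicted `x` and `P`.
#' @export
kf_predict <- function(x, P, A, x0, Q0) {
  A <- as.numeric(A)
  if (any(A < 0 | A > 1)) stop("entries of 'A' must lie in [0, 1]")
  if (length(A) != length(x) || length(x0) != length(x))
    stop("dimension mismatch in prediction")
  if (is.null(dim(Q0))) Q0 <- diag(as.numeric(Q0), length(x))
  xp <- A * x + (1 - A) * x0
  Pp <- (A %o% A) * P + Q0   # A diagonal: A P A' scales entries by a_i a_j
  list(x = xp, P = .spd_floor(Pp))
}

#' Information-form measurement update
#'
#' Assimilates scalar edge measurements `v_i` with measurement vectors `h_i`
#' and independent variances `r_i`:
#' `P_post^-1 = P_pred^-1 + sum h_i h_i' / r_i` and
#' `x_post = x_pred + P_post sum h_i v_i / r_i`.
#' With no measurements, state and covariance pass through unchanged.
#'
#' @param x Predicted state vector.
#' @param P Predicted covariance.
#' @param H Measurement matrix (n x dim(x)); row i is `h_i'`.
#' @param v Measured edge displacements (length n).
#' @param r Measurement variances (length n, all > 0).
#' @return List with posterior `x` and `P`.
#' @export
kf_update <- function(x, P, H, v, r) {
  if (is.null(H) || nrow(H) == 0) return(list(x = x, P = .spd_floor(P)))
  if (any(r <= 0)) stop("measurement variances must be positive")
  Hs <- H / sqrt(r)
  info <- .spd_solve(P) + crossprod(Hs)
  b <- colSums(H * (v / r))
  Ppost <- .spd_floor(.spd_solve(info))
  list(x = as.numeric(x + Ppost %*% b), P = Ppost)
}

#' Precision-weighted assimilation of forward and backward estimates
#'
#' Fuses two independent per-frame estimates by adding their information:
#' `P = (Pf^-1 + Pb^-1)^-1`, `x = P (Pf^-1 xf + Pb^-1 xb)`. Symmetric in its
#' arguments.
#'
#' @param xf,Pf Forward estimate and covariance.
#' @param xb,Pb Backward estimate and covariance.
#' @return List with fused `x` and `P`.
#' @export
kf_assimilate <- function(xf, Pf, xb, Pb) {
  If <- .spd_solve(Pf); Ib <- .spd_solve(Pb)
  P <- .spd_floor(.spd_solve(If + Ib))
  x <- as.numeric(P %*% (If %*% xf + Ib %*% xb))
  list(x = x, P = P)
}
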