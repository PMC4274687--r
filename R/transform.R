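# Global similarity transform T_g(p; x_g) = s Rx(tx) Ry(ty) Rz(tz) p + t and
# its derivatives. The full composite transform is T = T_g o T_l: the local
# radial deformation acts in the model frame, the similarity maps model to
# image space. State ordering is fixed: [t_x, t_y, t_z, s, th_x, th_y, th_z]
# then the local deformation states.

.rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
.rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
.rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
.drot_x <- function(a) matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
.drot_y <- function(a) matrix(c(-sin(a), 0, -cos(a), 0, 0, 0, cos(a), 0, -sin(a)), 3, 3)
.drot_z <- function(a) matrix(c(-sin(a), cos(a), 0, -cos(a), -sin(a), 0, 0, 0, 0), 3, 3)

#' Global similarity state
#'
#' Convenience constructor for the 7-element global state vector
#' `[t_x, t_y, t_z, s, theta_x, theta_y, theta_z]` (translation in mm, one
#' isotropic scale, rotation angles in radians, right-handed counter-clockwise,
#' composed as `Rx %*% Ry %*% Rz`).
#'
#' @param t Translation (length-3, mm).
#' @param s Scale (> 0).
#' @param theta Rotation angles (length-3, radians).
#' @return Numeric state vector of length 7.
#' @export
global_state <- function(t = c(0, 0, 0), s = 1, theta = c(0, 0, 0)) {
  if (s <= 0) stop("scale must be positive")
  c(t, s, theta)
}

# rotation matrix and its three angle derivatives for a global state
.tg_parts <- function(x_g) {
  th <- x_g[5:7]
  Rx <- .rot_x(th[1]); Ry <- .rot_y(th[2]); Rz <- .rot_z(th[3])
  R <- Rx %*% Ry %*% Rz
  list(R = R, s = x_g[4], t = x_g[1:3],
       dR = list(.drot_x(th[1]) %*% Ry %*% Rz,
                 Rx %*% .drot_y(th[2]) %*% Rz,
                 Rx %*% Ry %*% .drot_z(th[3])))
}

#' Apply the global similarity transform to points
#'
#' @param x_g Global state vector (see [global_state()]).
#' @param p A 3-vector or an n x 3 matrix of points (mm).
#' @return Transformed points, same shape as the input.
#' @export
transform_point <- function(x_g, p) {
  tp <- .tg_parts(x_g)
  single <- is.null(dim(p))
  P <- if (single) matrix(p, 1, 3) else p
  out <- tp$s * (P %*% t(tp$R)) + matrix(tp$t, nrow(P), 3, byrow = TRUE)
  if (single) as.numeric(out) else out
}

#' Transform one local sample to image space with full state Jacobian
#'
#' Maps a model-frame surface sample (position, unit normal, deformation
#' Jacobian) through the global similarity transform: position by the
#' transform itself, the normal by the inverse-transpose rule (then
#' renormalized; for a similarity this reduces to rotation), and the Jacobian
#' as the horizontal concatenation of the analytic derivative of the
#' transform with respect to the 7 global states and `M %*% J_l` where
#' `M = s R` is the point Jacobian.
#'
#' @param x Full state vector `[x_g; x_l]`.
#' @param p_l Model-frame position (3-vector).
#' @param n_l Model-frame unit normal (3-vector).
#' @param J_l 3 x n_local deformation Jacobian (may have zero columns for a
#'   rigid sample; pass a 3 x 0 matrix for a global-only state).
#' @return List with `p_g`, `n_g` (unit), `J_g` (3 x (7 + n_local)), and `M`.
#' @export
transform_sample <- function(x, p_l, n_l, J_l = matrix(0, 3, 0)) {
  x_g <- x[1:7]
  tp <- .tg_parts(x_g)
  M <- tp$s * tp$R
  p_g <- as.numeric(M %*% p_l + tp$t)
  # |M| M^{-T} n_l, renormalized; equals R n_l for a similarity
  ng <- as.numeric(det(M) * t(solve(M)) %*% n_l)
  ng <- ng / sqrt(sum(ng^2))
  Jg_global <- cbind(diag(3), tp$R %*% p_l,
                     tp$s * tp$dR[[1]] %*% p_l,
                     tp$s * tp$dR[[2]] %*% p_l,
                     tp$s * tp$dR[[3]] %*% p_l)
  J_g <- cbind(Jg_global, M %*% J_l)
  list(p_g = p_g, n_g = ng, J_g = J_g, M = M)
}

# Vectorized global mapping of a sample_surface() result. Returns image-space
# positions/normals and the measurement matrix H (n x dim(x)) with rows
# h_i^T = n_i^T J_i, built without forming per-sample Jacobians:
#   translation block: n_i
#   scale:             n_i . (R p_i)
#   rotation k:        n_i . (s dR_k p_i)
#   deformation j:     S[i, j] * n_i . (M d_j)
.transform_samples <- function(x_g, smp, dirs, with_local = TRUE) {
  tp <- .tg_parts(x_g)
  M <- tp$s * tp$R
  P_g <- smp$p_l %*% t(M) + matrix(tp$t, nrow(smp$p_l), 3, byrow = TRUE)
  N_g <- smp$n_l %*% t(tp$R)   # similarity: normals rotate
  RP <- smp$p_l %*% t(tp$R)
  H_global <- cbind(N_g,
                    rowSums(N_g * RP),
                    tp$s * rowSums(N_g * (smp$p_l %*% t(tp$dR[[1]]))),
                    tp$s * rowSums(N_g * (smp$p_l %*% t(tp$dR[[2]]))),
                    tp$s * rowSums(N_g * (smp$p_l %*% t(tp$dR[[3]]))))
  H <- if (with_local) cbind(H_global, smp$S * (N_g %*% (M %*% t(dirs)))) else H_global
  list(p_g = P_g, n_g = N_g, H = H)
}

#' Global pose aligning the model axis to an LVOT axis estimate
#'
#' Computes the global state that rotates the model z-axis onto a unit LVOT
#' long-axis direction (using the `Rx Ry Rz` angle convention, with zero spin
#' about the axis), translates the model origin (annulus disc centre) to a
#' given image-space point, and applies a given scale.
#'
#' @param axis Unit 3-vector, estimated LVOT long axis in image space.
#' @param center Image-space annulus centre guess (mm).
#' @param s Initial scale (default 1).
#' @return A global state vector (length 7).
#' @export
pose_from_axis <- function(axis, center, s = 1) {
  a <- axis / sqrt(sum(axis^2))
  # solve Rx(thx) Ry(thy) zhat = a: a = (sin thy, -sin thx cos thy, cos thx cos thy)
  thy <- asin(max(-1, min(1, a[1])))
  cy <- cos(thy)
  if (abs(cy) < 1e-9) {
    thx <- 0
  } else {
    thx <- atan2(-a[2] / cy, a[3] / cy)
  }
  global_state(t = center, s = s, theta = c(thx, thy, 0))
}

#' LVOT long axis from a recorded probe roll angle
#'
#' Convenience helper standing in for scanner roll-angle metadata: returns the
#' axis obtained by tilting the image z-axis by `tilt_deg` towards x and then
#' rolling about z by `roll_deg`.
#'
#' @param roll_deg Roll angle in degrees.
#' @param tilt_deg Tilt from the z-axis in degrees (default 0).
#' @return Unit 3-vector.
#' @export
lvot_axis_from_roll <- function(roll_deg, tilt_deg = 0) {
  r <- roll_deg * pi / 180; t <- tilt_deg * pi / 180
  as.numeric(.rot_z(r) %*% c(sin(t), 0, cos(t)))
}
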