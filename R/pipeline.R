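# Two-phase segmentation pipeline: stiff (7 global pose states, two forward
# sweeps) then deformable (full 37 states, bidirectional tracking with
# precision-weighted assimilation), followed by per-frame annulus
# quantification. fit_annulus() is the modelling front-end.

#' Initialization configuration
#'
#' @param center Initial annulus centre guess in image space (mm).
#' @param axis Estimated LVOT long axis (unit 3-vector; normalized here).
#' @param diameter Initial annulus diameter D0 (mm); plausibility-checked
#'   against `diameter_bounds`.
#' @param length Initial model length (mm).
#' @param diameter_bounds Allowed D0 range (default 10-50 mm).
#' @param ring_scale Relative ring radii of the initial surface (default the
#'   aortic-root template of [root_template_scale()]).
#' @return Object of class `annulus_init`.
#' @export
annulus_init <- function(center = c(0, 0, 0), axis = c(0, 0, 1), diameter = 25,
                         length = 40, diameter_bounds = c(10, 50),
                         ring_scale = root_template_scale()) {
  if (diameter < diameter_bounds[1] || diameter > diameter_bounds[2])
    stop("initial diameter ", diameter, " outside plausible range [",
         diameter_bounds[1], ", ", diameter_bounds[2], "] mm")
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("'axis' must be a nonzero vector")
  structure(list(center = as.numeric(center), axis = as.numeric(axis) / nrm,
                 diameter = diameter, length = length, ring_scale = ring_scale),
            class = "annulus_init")
}

#' Phase configuration (motion model and edge detection)
#'
#' Per-phase Kalman regularization and edge-detection settings. `A_*` are the
#' diagonal regularization entries per state class (in `[0, 1]`); `q_*` are
#' process-noise standard deviations.
#'
#' @param A_translation,A_scale,A_rotation,A_deformation Regularization
#'   diagonals per state class.
#' @param q_translation,q_scale,q_rotation Process noise SDs (mm, unitless,
#'   radians) used in the stiff phase.
#' @param q_deformation Deformation process noise SD (mm), deformable phase.
#' @param P0_translation,P0_scale,P0_rotation Initial SDs for the stiff
#'   phase.
#' @param edges An [edge_config()].
#' @return Object of class `phase_config`.
#' @export
phase_config <- function(A_translation = 0.9, A_scale = 0.95, A_rotation = 0.9,
                         A_deformation = 0.7,
                         q_translation = 2, q_scale = 0.05, q_rotation = 3 * pi / 180,
                         q_deformation = 1,
                         P0_translation = 10, P0_scale = 0.2, P0_rotation = 0.2,
                         edges = edge_config()) {
  av <- c(A_translation, A_scale, A_rotation, A_deformation)
  if (any(av < 0 | av > 1)) stop("regularization entries must lie in [0, 1]")
  structure(as.list(environment()), class = "phase_config")
}

#' Full segmentation control settings
#'
#' @param stiff Stiff-phase [phase_config()]; default uses a +/- 14 mm edge
#'   search (the capture range).
#' @param deformable Deformable-phase [phase_config()]; default raises the
#'   global-state regularization to 0.98 (increased confidence after the
#'   stiff phase) and narrows the edge search to +/- 7 mm.
#' @param n_angular,n_axial,n_disc Surface/disc sampling counts
#'   (default 20 x 15 tube points + 40 disc points).
#' @param levels Subdivision depth for surface evaluation.
#' @return Object of class `annulus_control`.
#' @export
annulus_control <- function(stiff = phase_config(edges = edge_config(search_mm = 14, n_samples = 29L)),
                            deformable = phase_config(A_translation = 0.98, A_scale = 0.98,
                                                      A_rotation = 0.98, A_deformation = 0.7,
                                                      edges = edge_config(search_mm = 7, n_samples = 15L)),
                            n_angular = 20L, n_axial = 15L, n_disc = 40L,
                            levels = 3L) {
  structure(list(stiff = stiff, deformable = deformable,
                 n_angular = as.integer(n_angular), n_axial = as.integer(n_axial),
                 n_disc = as.integer(n_disc), levels = as.integer(levels)),
            class = "annulus_control")
}

# diagonal vectors per state class for the 7 global states (+ n_l deformations)
.class_diag <- function(tr, sc, rot, def = NULL, n_l = 0L) {
  c(rep(tr, 3), sc, rep(rot, 3), rep(def %||% 0, n_l))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stiff segmentation pass
#'
#' Removes all deformation states and tracks only the 7-state global pose of
#' the model over the cycle: the initial mesh is posed from the
#' initialization config, then the Kalman filter sweeps once over all frames
#' for rough convergence and a second time for the recorded segmentation
#' (constant regularization state `x0` and process noise `Q0`).
#'
#' @param seq A [volume_sequence()].
#' @param mesh A `ds_mesh`.
#' @param init An [annulus_init()].
#' @param control An [annulus_control()].
#' @param x0 Optional explicit initial/regularization pose state (length 7);
#'   by default derived from `init` via [pose_from_axis()].
#' @return List with `x` (N x 7 matrix of per-frame poses), `P` (list of 7x7
#'   covariances), and `diagnostics` (per-frame accepted edge counts).
#' @export
run_stiff <- function(seq, mesh, init, control = annulus_control(), x0 = NULL) {
  cfg <- control$stiff
  N <- length(seq$frames)
  smp <- sample_surface(mesh, n_angular = control$n_angular, n_axial = control$n_axial,
                        n_disc = control$n_disc, levels = control$levels)
  if (is.null(x0)) x0 <- pose_from_axis(init$axis, init$center, s = 1)
  A <- .class_diag(cfg$A_translation, cfg$A_scale, cfg$A_rotation)
  Q0 <- diag(.class_diag(cfg$q_translation, cfg$q_scale, cfg$q_rotation)^2, 7)
  x <- x0
  P <- diag(.class_diag(cfg$P0_translation, cfg$P0_scale, cfg$P0_rotation)^2, 7)
  h_min <- cfg$edges$min_step_height %||% (0.1 * .robust_range(.seq_frame(seq, 1)))
  xs <- matrix(0, N, 7); Ps <- vector("list", N)
  n_acc <- integer(N)
  for (sweep in 1:2) {
    for (k in seq_len(N)) {
      pr <- kf_predict(x, P, A, x0, Q0)
      gmap <- .transform_samples(pr$x, smp, mesh$dirs, with_local = FALSE)
      meas <- .measure_edges(.seq_frame(seq, k), smp, gmap, cfg$edges, h_min)
      up <- kf_update(pr$x, pr$P, meas$H, meas$v, meas$r)
      # trust region: cap the per-frame translation and scale steps so
      # convergence from large initialization errors is gradual and outlier
      # rejection re-evaluates along the way (a one-sided edge set can
      # otherwise trade a lateral shift against a scale collapse)
      dt <- up$x[1:3] - pr$x[1:3]
      step <- sqrt(sum(dt^2))
      x <- if (step > 5) pr$x + (up$x - pr$x) * (5 / step) else up$x
      P <- up$P
      ds <- x[4] - pr$x[4]
      if (abs(ds) > 0.05) x[4] <- pr$x[4] + sign(ds) * 0.05
      x[4] <- min(max(x[4], 0.25), 4)  # scale stays a valid similarity
      if (sweep == 2) { xs[k, ] <- x; Ps[[k]] <- P; n_acc[k] <- meas$n_accepted }
    }
  }
  if (sum(n_acc == 0) > N / 2)
    stop("stiff segmentation failed: no accepted edges in more than half of the frames")
  list(x = xs, P = Ps, diagnostics = data.frame(frame = seq_len(N), n_accepted = n_acc))
}

# one full deformable filter pass over the given frame order
.deform_pass <- function(seq, mesh, smp, stiff, cfg, control, order, h_min) {
  n_l <- nrow(mesh$points)
  dim_x <- 7L + n_l
  A <- .class_diag(cfg$A_translation, cfg$A_scale, cfg$A_rotation, cfg$A_deformation, n_l)
  k0 <- order[1]
  x <- c(stiff$x[k0, ], numeric(n_l))
  P <- .block_Q(stiff$P[[k0]], cfg$q_deformation^2, n_l)
  xs <- matrix(0, length(order), dim_x); Ps <- vector("list", length(order))
  n_acc <- integer(length(order)); mav <- numeric(length(order))
  for (ii in seq_along(order)) {
    k <- order[ii]
    x0_k <- c(stiff$x[k, ], numeric(n_l))
    Q0_k <- .block_Q(stiff$P[[k]], cfg$q_deformation^2, n_l)
    pr <- kf_predict(x, P, A, x0_k, Q0_k)
    smp_k <- sample_surface(mesh, x_l = pr$x[8:dim_x], n_angular = control$n_angular,
                            n_axial = control$n_axial, n_disc = control$n_disc,
                            levels = control$levels)
    gmap <- .transform_samples(pr$x[1:7], smp_k, mesh$dirs, with_local = TRUE)
    meas <- .measure_edges(.seq_frame(seq, k), smp_k, gmap, cfg$edges, h_min)
    up <- kf_update(pr$x, pr$P, meas$H, meas$v, meas$r)
    x <- up$x; P <- up$P
    x[4] <- min(max(x[4], 0.25), 4)  # scale stays a valid similarity
    xs[ii, ] <- x; Ps[[ii]] <- P
    n_acc[ii] <- meas$n_accepted; mav[ii] <- meas$mean_abs_v
  }
  ord <- base::order(order)
  list(x = xs[ord, , drop = FALSE], P = Ps[ord],
       n_accepted = n_acc[ord], mean_abs_v = mav[ord])
}

.block_Q <- function(P_g, q_def_var, n_l) {
  Q <- diag(q_def_var, 7 + n_l)
  Q[1:7, 1:7] <- P_g
  Q
}

#' Deformable segmentation pass with bidirectional tracking
#'
#' Reintroduces the 30 radial deformation states. The stiff-phase per-frame
#' poses and covariances provide the motion-model regularization state
#' `x0_k = [x_stiff_k; 0]` and process noise
#' `Q0_k = blockdiag(P_stiff_k, q_def^2 I)`. Independent forward and
#' backward passes (both initialized from the stiff result) are fused per
#' frame by precision-weighted assimilation, which keeps the segmentation
#' from lagging the motion of the aortic root.
#'
#' @param seq A [volume_sequence()].
#' @param mesh A `ds_mesh`.
#' @param stiff Result of [run_stiff()].
#' @param control An [annulus_control()].
#' @return List with per-frame assimilated `x` (N x 37), `P`, forward and
#'   backward passes, and diagnostics.
#' @export
run_deformable <- function(seq, mesh, stiff, control = annulus_control()) {
  cfg <- control$deformable
  N <- length(seq$frames)
  if (nrow(stiff$x) != N) stop("stiff result does not cover all frames")
  smp <- sample_surface(mesh, n_angular = control$n_angular, n_axial = control$n_axial,
                        n_disc = control$n_disc, levels = control$levels)
  h_min <- cfg$edges$min_step_height %||% (0.1 * .robust_range(.seq_frame(seq, 1)))
  fwd <- .deform_pass(seq, mesh, smp, stiff, cfg, control, seq_len(N), h_min)
  bwd <- .deform_pass(seq, mesh, smp, stiff, cfg, control, rev(seq_len(N)), h_min)
  xs <- matrix(0, N, ncol(fwd$x)); Ps <- vector("list", N)
  for (k in seq_len(N)) {
    as_k <- kf_assimilate(fwd$x[k, ], fwd$P[[k]], bwd$x[k, ], bwd$P[[k]])
    xs[k, ] <- as_k$x; Ps[[k]] <- as_k$P
  }
  list(x = xs, P = Ps, forward = fwd, backward = bwd,
       diagnostics = data.frame(frame = seq_len(N),
                                n_accepted_fwd = fwd$n_accepted,
                                n_accepted_bwd = bwd$n_accepted,
                                mean_abs_v_fwd = fwd$mean_abs_v,
                                mean_abs_v_bwd = bwd$mean_abs_v))
}

# Axial template-matching scan: slide the posed model along its own long
# axis and score the edge agreement, returning the best axial shift. The
# waist/bulge template makes this a well-posed 1D localization of the
# annulus level; the Kalman updates alone can be trapped by the
# scale/axial-shift coupling when the initial centre is far off axially.
.axial_scan <- function(seq, mesh, x0, control, range_mm = 14, step_mm = 2) {
  cfg <- control$stiff
  # coarse profiles suffice: the scan only needs the right 2 mm basin,
  # which the stiff filter then refines
  ecfg <- cfg$edges
  ecfg$n_samples <- 15L
  smp <- sample_surface(mesh, n_angular = control$n_angular, n_axial = control$n_axial,
                        n_disc = control$n_disc, levels = control$levels)
  vol <- .seq_frame(seq, 1)
  h_min <- cfg$edges$min_step_height %||% (0.1 * .robust_range(vol))
  axis_w <- .tg_parts(x0)$R %*% c(0, 0, 1)
  cand <- seq(-range_mm, range_mm, by = step_mm)
  score <- rep(Inf, length(cand))
  for (i in seq_along(cand)) {
    xc <- x0
    xc[1:3] <- xc[1:3] + cand[i] * axis_w
    gmap <- .transform_samples(xc, smp, mesh$dirs, with_local = FALSE)
    meas <- .measure_edges(vol, smp, gmap, ecfg, h_min)
    if (meas$n_accepted < meas$n_total / 4) next
    # close, plentiful edges win: median residual displacement plus a
    # capture-range penalty for sparse edge support
    score[i] <- stats::median(abs(meas$v)) +
      ecfg$search_mm * (1 - meas$n_accepted / meas$n_total)
  }
  if (all(!is.finite(score))) return(0)
  # only move when the shift improves the fit decisively over staying put:
  # under a mostly-lateral initialization error the axial score landscape
  # is uninformative noise, and the stiff filter recovers laterally on its
  # own; the post-renormalization rescan then fixes any axial residue
  s0 <- score[cand == 0]
  sb <- min(score)
  if (length(s0) == 1 && is.finite(s0) && sb > s0 - 1) return(0)
  cand[which.min(score)]
}

# annulus measurement for one frame state
.measure_annulus <- function(mesh, x, levels) {
  n_l <- nrow(mesh$points)
  x_g <- x[1:7]; x_l <- x[8:(7 + n_l)]
  sub <- ds_subdivide(apply_local_deform(mesh, x_l), levels)
  verts <- transform_point(x_g, sub$vertices)
  tp <- .tg_parts(x_g)
  center <- as.numeric(tp$t)              # model origin is the disc centre
  normal <- as.numeric(tp$R %*% c(0, 0, 1))
  pts <- intersect_annulus(verts, sub$faces, center, normal)
  if (is.null(pts)) return(NULL)
  b <- .plane_basis(normal)
  rel <- pts - matrix(center, nrow(pts), 3, byrow = TRUE)
  xy <- cbind(rel %*% b$e1, rel %*% b$e2)
  el <- fit_ellipse(xy)
  if (is.null(el)) return(NULL)
  m <- ellipse_measures(el)
  center3 <- center + el$center[1] * b$e1 + el$center[2] * b$e2
  c(list(center = center3, normal = normal, points = pts, ellipse = el), m)
}

#' Fit the annulus model to a volume sequence
#'
#' The package's main entry point: runs the full two-phase tracking
#' (stiff pose estimation, then deformable bidirectional tracking with
#' assimilation) and quantifies the annulus in every frame by intersecting
#' the deformed surface with the annulus disc plane and fitting an ellipse.
#' Mid systole is the frame of maximum detected annulus area.
#'
#' The fit is deterministic: identical inputs give identical results.
#' Pathological inputs (e.g. pure noise with no detectable wall) yield an
#' object with `status = "failed"` and diagnostics rather than an error.
#'
#' @param seq A [volume_sequence()] covering one cardiac cycle.
#' @param init An [annulus_init()] (axis, centre, initial diameter).
#' @param control An [annulus_control()].
#' @return Object of class `annulus_fit` with components `frames` (per-frame
#'   measurement table), `mid_systole`, `states`, `covariances`, `stiff`,
#'   `mesh`, `diagnostics`, `status` and the configs used.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_config(speckle_level = 0, translation_amp = 0,
#'                                       rotation_amp_deg = 0), seed = 1)
#' fit <- fit_annulus(ph$sequence, annulus_init(center = c(0, 0, 0)))
#' summary(fit)
#' }
#' @export
fit_annulus <- function(seq, init = annulus_init(), control = annulus_control()) {
  stopifnot(inherits(seq, "volume_sequence"))
  out <- tryCatch(.fit_annulus_impl(seq, init, control), error = function(e) {
    structure(list(status = "failed", message = conditionMessage(e),
                   frames = NULL, mid_systole = NA_integer_,
                   init = init, control = control),
              class = "annulus_fit")
  })
  out
}

.fit_annulus_impl <- function(seq, init, control) {
  mesh <- ds_mesh(init$diameter, init$length, ring_scale = init$ring_scale)
  # resolve the annulus level along the initial axis before any tracking:
  # axial initialization errors (up to the capture range) are a known trap
  # for the scale/axial-shift coupling of the similarity transform
  x0 <- pose_from_axis(init$axis, init$center, s = 1)
  dz0 <- .axial_scan(seq, mesh, x0, control)
  x0[1:3] <- x0[1:3] + dz0 * (.tg_parts(x0)$R %*% c(0, 0, 1))
  stiff <- run_stiff(seq, mesh, init, control, x0 = x0)
  # scale normalization: rebuild the model at the estimated diameter so the
  # result does not depend on the initial diameter guess D0 (the isotropic
  # scale otherwise couples the model length, and with it the axial template
  # alignment, to D0), then repeat the stiff pass from the estimated pose
  s_med <- stats::median(stiff$x[, 4])
  mesh2 <- ds_mesh(init$diameter * s_med, init$length, ring_scale = init$ring_scale)
  x0 <- c(apply(stiff$x[, 1:3, drop = FALSE], 2, stats::median), 1,
          apply(stiff$x[, 5:7, drop = FALSE], 2, stats::median))
  # axial template-matching scan resolves the annulus level explicitly
  dz <- .axial_scan(seq, mesh2, x0, control)
  if (abs(s_med - 1) > 0.02 || abs(dz) > 0.5) {
    mesh <- mesh2
    x0[1:3] <- x0[1:3] + dz * (.tg_parts(x0)$R %*% c(0, 0, 1))
    stiff <- run_stiff(seq, mesh, init, control, x0 = x0)
  }
  def <- run_deformable(seq, mesh, stiff, control)
  N <- length(seq$frames)
  rows <- vector("list", N)
  details <- vector("list", N)
  for (k in seq_len(N)) {
    m <- .measure_annulus(mesh, def$x[k, ], control$levels)
    details[[k]] <- m
    rows[[k]] <- if (is.null(m)) {
      data.frame(frame = k, valid = FALSE, center_x = NA, center_y = NA, center_z = NA,
                 major_d = NA, minor_d = NA, area = NA, perimeter = NA,
                 area_derived_d = NA, perimeter_derived_d = NA)
    } else {
      data.frame(frame = k, valid = TRUE, center_x = m$center[1], center_y = m$center[2],
                 center_z = m$center[3], major_d = m$major_d, minor_d = m$minor_d,
                 area = m$area, perimeter = m$perimeter,
                 area_derived_d = m$area_derived_d,
                 perimeter_derived_d = m$perimeter_derived_d)
    }
  }
  frames <- do.call(rbind, rows)
  if (!any(frames$valid)) stop("annulus measurement failed in every frame")
  mid <- select_mid_systole(ifelse(frames$valid, frames$area, NA))
  structure(list(status = "ok", frames = frames, mid_systole = mid,
                 states = def$x, covariances = def$P, stiff = stiff,
                 deformable_diagnostics = def$diagnostics,
                 details = details, mesh = mesh, init = init, control = control,
                 frame_times = seq$frame_times),
            class = "annulus_fit")
}

#' Sensitivity analysis of the automatic measurement to initialization
#'
#' Re-runs the full segmentation under random perturbations of the initial
#' state (the protocol used to validate robustness to the roll-angle derived
#' LVOT axis): translations of the initial centre by `d n/||n||` with `n`
#' uniform on `[-1, 1]^3`, rotations of the initial model by an angle about
#' a random line through the initial annulus centre, or a deterministic
#' sweep of the initial annulus diameter D0. The mid-systolic
#' perimeter-derived diameter of each run is recorded.
#'
#' @param seq A [volume_sequence()].
#' @param init Baseline [annulus_init()].
#' @param protocol `"translation"`, `"rotation"` or `"scaling"`.
#' @param magnitudes Perturbation magnitudes: mm for translation (default
#'   `c(2, 4, 6, 8, 10, 12)`), degrees for rotation (default `1:15`), or the
#'   D0 sweep in mm for scaling (default 100 values linearly spaced over
#'   15-35 mm).
#' @param n_reps Random repetitions per magnitude (ignored for scaling).
#' @param seed RNG seed.
#' @param control An [annulus_control()].
#' @return Object of class `annulus_sensitivity`: a data frame with one row
#'   per magnitude (`mean`, `sd`, `n_ok`, `n_failed`) plus the raw
#'   per-run diameters in `attr(, "runs")`.
#' @export
sensitivity_analysis <- function(seq, init, protocol = c("translation", "rotation", "scaling"),
                                 magnitudes = NULL, n_reps = 50L, seed = 1L,
                                 control = annulus_control()) {
  protocol <- match.arg(protocol)
  if (is.null(magnitudes))
    magnitudes <- switch(protocol,
                         translation = seq(2, 12, by = 2),
                         rotation = 1:15,
                         scaling = seq(15, 35, length.out = 100))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  run_one <- function(ini) {
    fit <- fit_annulus(seq, ini, control)
    if (fit$status != "ok" || is.na(fit$mid_systole)) return(NA_real_)
    fit$frames$perimeter_derived_d[fit$mid_systole]
  }
  runs <- list()
  for (m in magnitudes) {
    if (protocol == "scaling") {
      vals <- run_one(annulus_init(init$center, init$axis, diameter = m,
                                   length = init$length, ring_scale = init$ring_scale))
    } else {
      vals <- vapply(seq_len(n_reps), function(rep) {
        n <- stats::runif(3, -1, 1)
        n <- n / sqrt(sum(n^2))
        ini <- if (protocol == "translation") {
          annulus_init(init$center + m * n, init$axis, init$diameter, init$length,
                       ring_scale = init$ring_scale)
        } else {
          R <- .axis_angle(n, m * pi / 180)
          annulus_init(init$center, as.numeric(R %*% init$axis),
                       init$diameter, init$length, ring_scale = init$ring_scale)
        }
        run_one(ini)
      }, numeric(1))
    }
    runs[[as.character(m)]] <- vals
  }
  if (protocol == "scaling") {
    v <- unlist(runs)
    tab <- data.frame(magnitude = NA_real_, mean = mean(v, na.rm = TRUE),
                      sd = stats::sd(v[!is.na(v)]),
                      n_ok = sum(!is.na(v)), n_failed = sum(is.na(v)))
  } else {
    tab <- do.call(rbind, lapply(names(runs), function(nm) {
      v <- runs[[nm]]
      data.frame(magnitude = as.numeric(nm), mean = mean(v, na.rm = TRUE),
                 sd = if (sum(!is.na(v)) > 1) stats::sd(v[!is.na(v)]) else 0,
                 n_ok = sum(!is.na(v)), n_failed = sum(is.na(v)))
    }))
  }
  structure(tab, runs = runs, protocol = protocol, class = c("annulus_sensitivity", "data.frame"))
}

#' @export
print.annulus_sensitivity <- function(x, ...) {
  cat("Sensitivity analysis (", attr(x, "protocol"), " protocol)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
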