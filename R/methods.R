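# S3 methods for the fitted model object.

#' @export
print.annulus_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat("annulus_fit: FAILED -", x$message, "\n")
    return(invisible(x))
  }
  n <- nrow(x$frames)
  ms <- x$mid_systole
  cat("Automatic aortic annulus measurement (EKF subdivision-surface fit)\n")
  cat(sprintf("  %d frames, %d valid; mid-systole frame %d\n",
              n, sum(x$frames$valid), ms))
  cat(sprintf("  perimeter-derived diameter at mid-systole: %.2f mm\n",
              x$frames$perimeter_derived_d[ms]))
  invisible(x)
}

#' Summary of an annulus fit
#'
#' @param object An `annulus_fit`.
#' @param ... Unused.
#' @return A `summary.annulus_fit`: mid-systolic measures and the per-frame
#'   table.
#' @export
summary.annulus_fit <- function(object, ...) {
  if (object$status != "ok") {
    out <- list(status = object$status, message = object$message)
    class(out) <- "summary.annulus_fit"
    return(out)
  }
  ms <- object$mid_systole
  row <- object$frames[ms, ]
  out <- list(status = "ok",
              mid_systole = ms,
              measures = c(major_d = row$major_d, minor_d = row$minor_d,
                           area = row$area, perimeter = row$perimeter,
                           area_derived_d = row$area_derived_d,
                           perimeter_derived_d = row$perimeter_derived_d),
              frames = object$frames)
  class(out) <- "summary.annulus_fit"
  out
}

#' @export
print.summary.annulus_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat("annulus_fit: FAILED -", x$message, "\n")
    return(invisible(x))
  }
  cat("Mid-systolic annulus measures (frame", x$mid_systole, "):\n")
  m <- x$measures
  cat(sprintf("  major diameter     %6.2f mm\n", m["major_d"]))
  cat(sprintf("  minor diameter     %6.2f mm\n", m["minor_d"]))
  cat(sprintf("  area               %6.1f mm^2\n", m["area"]))
  cat(sprintf("  perimeter          %6.1f mm\n", m["perimeter"]))
  cat(sprintf("  area-derived D     %6.2f mm\n", m["area_derived_d"]))
  cat(sprintf("  perimeter-derived D %5.2f mm  (main output)\n", m["perimeter_derived_d"]))
  cat("\nPer-frame measurements:\n")
  print(x$frames[, c("frame", "valid", "area", "perimeter",
                     "area_derived_d", "perimeter_derived_d")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-frame state estimates of an annulus fit
#'
#' @param object An `annulus_fit`.
#' @param ... Unused.
#' @return N x 37 matrix of assimilated states (7 global pose states
#'   followed by the 30 radial deformation states).
#' @export
coef.annulus_fit <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  x <- object$states
  n_l <- nrow(object$mesh$points)
  colnames(x) <- c("t_x", "t_y", "t_z", "s", "theta_x", "theta_y", "theta_z",
                   paste0("d", seq_len(n_l)))
  x
}

#' @export
fitted.annulus_fit <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  object$frames$perimeter_derived_d
}

#' Edge innovation residuals of an annulus fit
#'
#' Mean absolute detected edge displacement per frame in the deformable
#' passes (mm): how far the surface still was from the detected edges when
#' each frame was processed.
#'
#' @param object An `annulus_fit`.
#' @param ... Unused.
#' @return Data frame with forward/backward per-frame residuals.
#' @export
residuals.annulus_fit <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  object$deformable_diagnostics[, c("frame", "mean_abs_v_fwd", "mean_abs_v_bwd")]
}

#' Predict surface points or diameters from an annulus fit
#'
#' @param object An `annulus_fit`.
#' @param frames Frame indices (default all).
#' @param what `"surface"` (image-space subdivision surface vertices per
#'   frame) or `"diameter"` (perimeter-derived diameters).
#' @param ... Unused.
#' @return List of vertex matrices, or a numeric vector of diameters.
#' @export
predict.annulus_fit <- function(object, frames = NULL, what = c("surface", "diameter"), ...) {
  if (object$status != "ok") return(NULL)
  what <- match.arg(what)
  if (is.null(frames)) frames <- seq_len(nrow(object$frames))
  if (what == "diameter") return(object$frames$perimeter_derived_d[frames])
  n_l <- nrow(object$mesh$points)
  lapply(frames, function(k) {
    x <- object$states[k, ]
    sub <- ds_subdivide(apply_local_deform(object$mesh, x[8:(7 + n_l)]), object$control$levels)
    list(vertices = transform_point(x[1:7], sub$vertices), faces = sub$faces)
  })
}

#' Plot an annulus fit
#'
#' Per-frame area-derived and perimeter-derived diameters with the
#' mid-systolic frame marked.
#'
#' @param x An `annulus_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.annulus_fit <- function(x, ...) {
  if (x$status != "ok") stop("cannot plot a failed fit")
  f <- x$frames
  graphics::matplot(f$frame, cbind(f$perimeter_derived_d, f$area_derived_d),
                    type = "b", pch = c(19, 1), lty = 1,
                    xlab = "frame", ylab = "diameter [mm]",
                    main = "Automatic annulus diameter over the cycle", ...)
  graphics::abline(v = x$mid_systole, lty = 2)
  graphics::legend("bottomright", c("perimeter-derived", "area-derived", "mid-systole"),
                   pch = c(19, 1, NA), lty = c(1, 1, 2), bty = "n")
  invisible(x)
}
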