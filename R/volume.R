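# In-memory 3D volume and volume-sequence containers with physical (mm)
# voxel geometry, plus trilinear interpolation. World coordinates follow the
# NIfTI affine convention: world = origin + (index - 1) * spacing, axes
# RAS-like with a positive diagonal affine.

#' Create a 3D volume with physical geometry
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Voxel spacing in mm (length 3, all > 0).
#' @param origin World coordinate (mm) of the first voxel centre.
#' @return Object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(data = data, spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d: %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = ", "),
              paste(format(x$origin, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Ordered sequence of 3D volumes over one cardiac cycle
#'
#' All frames must share grid dimensions, spacing and origin.
#'
#' @param frames List of 3D arrays or `volume3d` objects.
#' @param spacing,origin Geometry shared by all frames (taken from the first
#'   `volume3d` if frames are volumes).
#' @param frame_times Acquisition times in seconds (default evenly spaced at
#'   `1/frame_rate`).
#' @param frame_rate Volumes per second (default 10).
#' @return Object of class `volume_sequence`.
#' @export
volume_sequence <- function(frames, spacing = NULL, origin = NULL,
                            frame_times = NULL, frame_rate = 10) {
  if (length(frames) < 1L) stop("need at least one frame")
  if (inherits(frames[[1]], "volume3d")) {
    if (is.null(spacing)) spacing <- frames[[1]]$spacing
    if (is.null(origin)) origin <- frames[[1]]$origin
    frames <- lapply(frames, function(f) f$data)
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(origin)) origin <- c(0, 0, 0)
  d1 <- dim(frames[[1]])
  for (k in seq_along(frames)) {
    if (!identical(dim(frames[[k]]), d1))
      stop("frame ", k, " has dimensions ", paste(dim(frames[[k]]), collapse = "x"),
           ", expected ", paste(d1, collapse = "x"))
  }
  if (is.null(frame_times)) frame_times <- (seq_along(frames) - 1) / frame_rate
  structure(list(frames = frames, spacing = rep_len(as.numeric(spacing), 3L),
                 origin = rep_len(as.numeric(origin), 3L),
                 frame_times = as.numeric(frame_times)),
            class = "volume_sequence")
}

#' @export
print.volume_sequence <- function(x, ...) {
  cat(sprintf("volume_sequence: %d frames of %s voxels @ %s mm\n",
              length(x$frames), paste(dim(x$frames[[1]]), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = ", ")))
  invisible(x)
}

#' @export
length.volume_sequence <- function(x) length(x$frames)

# frame k as a volume3d
.seq_frame <- function(seq, k) volume3d(seq$frames[[k]], seq$spacing, seq$origin)

#' Trilinear interpolation of a volume at world points
#'
#' @param vol A `volume3d`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return Numeric vector of length n; `NA` for points outside the grid.
#' @export
interp_trilinear <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  d <- dim(vol$data)
  # continuous voxel coordinates, 1-based
  cx <- (pts[, 1] - vol$origin[1]) / vol$spacing[1] + 1
  cy <- (pts[, 2] - vol$origin[2]) / vol$spacing[2] + 1
  cz <- (pts[, 3] - vol$origin[3]) / vol$spacing[3] + 1
  ok <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3] &
    is.finite(cx) & is.finite(cy) & is.finite(cz)
  out <- rep(NA_real_, length(cx))
  if (!any(ok)) return(out)
  x0 <- pmin(floor(cx[ok]), d[1] - 1); fx <- cx[ok] - x0
  y0 <- pmin(floor(cy[ok]), d[2] - 1); fy <- cy[ok] - y0
  z0 <- pmin(floor(cz[ok]), d[3] - 1); fz <- cz[ok] - z0
  n12 <- d[1] * d[2]
  base <- (z0 - 1) * n12 + (y0 - 1) * d[1] + x0
  v <- vol$data
  c000 <- v[base];                 c100 <- v[base + 1]
  c010 <- v[base + d[1]];          c110 <- v[base + d[1] + 1]
  c001 <- v[base + n12];           c101 <- v[base + n12 + 1]
  c011 <- v[base + n12 + d[1]];    c111 <- v[base + n12 + d[1] + 1]
  out[ok] <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * c000 + fx * c100) +
                fy * ((1 - fx) * c010 + fx * c110)) +
    fz * ((1 - fy) * ((1 - fx) * c001 + fx * c101) +
          fy * ((1 - fx) * c011 + fx * c111))
  out
}

# robust intensity range (1%-99% quantiles), used for edge-height thresholds
.robust_range <- function(vol) {
  q <- stats::quantile(vol$data, c(0.01, 0.99), names = FALSE)
  max(q[2] - q[1], .Machine$double.eps)
}
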