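# Edge detection along surface normals: 1D intensity profile extraction,
# least-squares step / peak template fitting, neighbourhood outlier
# rejection, and measurement-noise normalization (sum of variances fixed to
# r_edge so total measurement information is a single tunable).

#' Edge-detection configuration
#'
#' @param search_mm Half-width of the search range along the normal (mm);
#'   this sets the capture range of the tracker.
#' @param n_samples Number of profile samples (odd, so the surface point
#'   itself is sampled).
#' @param fit_model `"step"`, `"peak"` or `"auto"` (fit both, keep the lower
#'   residual; in echo the wall can present as either).
#' @param min_step_height Minimum fitted edge amplitude for acceptance;
#'   `NULL` (default) resolves at run time to 10% of the volume's robust
#'   (1-99% quantile) intensity range.
#' @param neighbor_max_delta_mm Maximum allowed deviation of an edge
#'   displacement from the median of its grid neighbours (mm).
#' @param r_edge Total normalized measurement variance (mm^2): after
#'   normalization the per-edge variances sum to this value.
#' @return Object of class `edge_config`.
#' @export
edge_config <- function(search_mm = 14, n_samples = 29L, fit_model = c("auto", "step", "peak"),
                        min_step_height = NULL, neighbor_max_delta_mm = 3, r_edge = 100) {
  if (search_mm <= 0) stop("'search_mm' must be positive")
  if (r_edge <= 0) stop("'r_edge' must be positive")
  n_samples <- as.integer(n_samples)
  if (n_samples < 5L) stop("need at least 5 profile samples")
  if (n_samples %% 2L == 0L) n_samples <- n_samples + 1L
  structure(list(search_mm = search_mm, n_samples = n_samples,
                 fit_model = match.arg(fit_model),
                 min_step_height = min_step_height,
                 neighbor_max_delta_mm = neighbor_max_delta_mm,
                 r_edge = r_edge),
            class = "edge_config")
}

#' Extract intensity profiles along normals
#'
#' Samples the volume by trilinear interpolation at `n_samples` points
#' symmetric about each surface point along its image-space normal, covering
#' `+/- search_mm`. Profiles with fewer than half of their samples inside the
#' volume are flagged unusable; remaining out-of-volume samples are filled by
#' nearest-valid extension.
#'
#' @param vol A `volume3d`.
#' @param p_g n x 3 image-space surface points (mm).
#' @param n_g n x 3 unit image-space normals.
#' @param config An [edge_config()].
#' @return List with `intensities` (n x K matrix), `offsets` (signed mm
#'   positions along the normal) and `usable` (logical n).
#' @export
extract_profiles <- function(vol, p_g, n_g, config) {
  K <- config$n_samples
  offsets <- seq(-config$search_mm, config$search_mm, length.out = K)
  n <- nrow(p_g)
  # all n*K sample points at once
  pts <- matrix(0, n * K, 3)
  for (a in 1:3)
    pts[, a] <- rep(p_g[, a], K) + rep(offsets, each = n) * rep(n_g[, a], K)
  X <- matrix(interp_trilinear(vol, pts), n, K)
  n_valid <- rowSums(!is.na(X))
  usable <- n_valid >= K / 2
  if (anyNA(X)) {
    for (i in which(usable & rowSums(is.na(X)) > 0)) {
      xi <- X[i, ]
      good <- which(!is.na(xi))
      X[i, ] <- xi[good][pmax(1, findInterval(seq_len(K), good, all.inside = FALSE))]
      # findInterval gives the last valid index at or before each position;
      # positions before the first valid sample take the first valid value
      X[i, seq_len(K) < good[1]] <- xi[good[1]]
    }
    X[is.na(X)] <- 0  # unusable rows; masked out via `usable`
  }
  list(intensities = X, offsets = offsets, usable = usable)
}

# segment sum-of-squared-deviation helper from row cumsums
.seg_sse <- function(cs, cs2, a, b) {
  n <- b - a + 1
  s <- cs[, b + 1] - cs[, a]
  s2 <- cs2[, b + 1] - cs2[, a]
  s2 - s^2 / n   # may be ~ -1e-12 from cancellation; clamped by consumers
}
.seg_mean <- function(cs, a, b) (cs[, b + 1] - cs[, a]) / (b - a + 1)

#' Least-squares step/peak edge fit on intensity profiles
#'
#' For each profile, fits (a) a two-plateau step template at every candidate
#' transition and/or (b) a plateau-peak-plateau template at every candidate
#' transition pair, by least squares (plateau values are segment means), and
#' keeps the minimum-residual candidate. The edge displacement is the offset
#' of the transition midpoint (step) or of the peak centre (peak). Profiles
#' where no candidate beats the flat fit are rejected.
#'
#' @param profiles Result of [extract_profiles()] (or a compatible list).
#' @param config An [edge_config()].
#' @return Data frame with one row per profile: `v` (mm), `residual` (sum of
#'   squared deviations), `step_height`, `model` and `ok`.
#' @export
fit_edges <- function(profiles, config) {
  X <- profiles$intensities
  off <- profiles$offsets
  n <- nrow(X); K <- ncol(X)
  U <- upper.tri(matrix(0, K, K), diag = TRUE)  # row-wise cumsum via matmul
  cs <- cbind(0, X %*% U)
  cs2 <- cbind(0, X^2 %*% U)
  flat <- .seg_sse(cs, cs2, 1L, K)
  best_sse <- rep(Inf, n); best_v <- rep(NA_real_, n)
  best_h <- rep(0, n); best_model <- rep(NA_character_, n)
  fitstep <- config$fit_model %in% c("step", "auto")
  fitpeak <- config$fit_model %in% c("peak", "auto")
  if (fitstep) {
    for (j in 2:(K - 2)) {  # >= 2 samples on each side
      sse <- .seg_sse(cs, cs2, 1L, j) + .seg_sse(cs, cs2, j + 1L, K)
      upd <- sse < best_sse
      if (any(upd)) {
        h <- abs(.seg_mean(cs, j + 1L, K) - .seg_mean(cs, 1L, j))
        best_v[upd] <- (off[j] + off[j + 1]) / 2
        best_h[upd] <- h[upd]
        best_sse[upd] <- sse[upd]
        best_model[upd] <- "step"
      }
    }
  }
  if (fitpeak) {
    jj <- 1:(K - 1)
    # prefix/suffix segment SSEs and means for all split points at once
    pre_len <- matrix(jj, n, K - 1, byrow = TRUE)
    suf_len <- matrix(K - jj, n, K - 1, byrow = TRUE)
    PreS <- cs2[, jj + 1, drop = FALSE] - cs[, jj + 1, drop = FALSE]^2 / pre_len
    PreM <- cs[, jj + 1, drop = FALSE] / pre_len
    SufSum <- cs[, K + 1] - cs[, jj + 1, drop = FALSE]
    SufS <- (cs2[, K + 1] - cs2[, jj + 1, drop = FALSE]) - SufSum^2 / suf_len
    SufM <- SufSum / suf_len
    for (j1 in 2:(K - 3)) {
      b2 <- (j1 + 1):(K - 2)
      len <- matrix(b2 - j1, n, length(b2), byrow = TRUE)
      Sm <- cs[, b2 + 1, drop = FALSE] - cs[, j1 + 1]
      S2m <- cs2[, b2 + 1, drop = FALSE] - cs2[, j1 + 1]
      sse <- PreS[, j1] + (S2m - Sm^2 / len) + SufS[, b2, drop = FALSE]
      # bright-peak template: the wall is brighter than lumen/background
      mp <- Sm / len
      h <- pmin(mp - PreM[, j1], mp - SufM[, b2, drop = FALSE])
      sse[h <= 0] <- Inf
      jbest <- max.col(-sse, ties.method = "first")
      pick <- cbind(seq_len(n), jbest)
      sse_b <- sse[pick]
      upd <- which(sse_b < best_sse)
      if (length(upd)) {
        j2 <- b2[jbest[upd]]
        best_v[upd] <- (off[j1] + off[j1 + 1] + off[j2] + off[j2 + 1]) / 4
        best_h[upd] <- h[pick][upd]
        best_sse[upd] <- sse_b[upd]
        best_model[upd] <- "peak"
      }
    }
  }
  ok <- profiles$usable & is.finite(best_v) &
    best_sse < flat * (1 - 1e-9) - 1e-12 & best_h > 0
  data.frame(v = best_v, residual = pmax(best_sse, 0), step_height = best_h,
             model = best_model, ok = ok, stringsAsFactors = FALSE)
}

#' Reject outlier edges
#'
#' Rejects edges whose fitted amplitude is below `min_step_height` or whose
#' displacement deviates from the median displacement of their accepted grid
#' neighbours by more than `neighbor_max_delta_mm`. A single order-independent
#' sweep: neighbour statistics are computed from the pre-sweep accepted set.
#'
#' @param edges Data frame from [fit_edges()] (columns `v`, `step_height`,
#'   `ok`).
#' @param neighbors List of integer neighbour-index vectors, one per edge
#'   (from the surface sampling grid).
#' @param config An [edge_config()] whose `min_step_height` has been resolved
#'   to a number.
#' @return The data frame with `ok` updated.
#' @export
reject_outliers <- function(edges, neighbors, config) {
  h_min <- config$min_step_height
  if (is.null(h_min)) h_min <- 0
  pre <- edges$ok & edges$step_height >= h_min  # pre-sweep accepted set
  n <- length(pre)
  deg <- max(lengths(neighbors))
  NB <- matrix(NA_integer_, n, deg)
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (length(nb)) NB[i, seq_along(nb)] <- nb
  }
  vm <- matrix(edges$v[NB], n, deg)
  vm[!matrix(pre[NB], n, deg) %in% TRUE] <- NA
  cnt <- rowSums(!is.na(vm))
  sm <- rowSums(vm, na.rm = TRUE)
  cols <- lapply(seq_len(deg), function(j) vm[, j])
  mn <- do.call(pmin, c(cols, list(na.rm = TRUE)))
  mx <- do.call(pmax, c(cols, list(na.rm = TRUE)))
  med <- ifelse(cnt >= 4, (sm - mn - mx) / 2,          # median of 4
         ifelse(cnt == 3, sm - mn - mx,                # middle of 3
         ifelse(cnt >= 1, sm / pmax(cnt, 1), NA)))     # mean of <= 2
  ok <- pre & (cnt == 0 | is.na(med) |
               abs(edges$v - med) <= config$neighbor_max_delta_mm)
  edges$ok <- ok & pre
  edges
}

#' Normalize edge measurement variances
#'
#' Scales the raw per-edge variances (fit residuals) so their sum equals
#' `r_edge`, guarding zero residuals with a small epsilon so noiseless fits
#' do not claim infinite confidence.
#'
#' @param residuals Non-negative raw variances of the accepted edges.
#' @param r_edge Target total variance (mm^2).
#' @return Normalized variances summing exactly to `r_edge`; `numeric(0)` for
#'   an empty input (no measurement update).
#' @export
normalize_variances <- function(residuals, r_edge) {
  if (length(residuals) == 0) return(numeric(0))
  if (any(residuals < 0)) stop("residuals must be non-negative")
  eps <- 1e-6 * max(max(residuals), 1)
  w <- residuals + eps
  r_edge * w / sum(w)
}

# 4-neighbourhood (angular wrap, axial clamp) of the tube sampling grid plus
# ring neighbourhood of the disc samples, as a list of index vectors
.nb_cache <- new.env(parent = emptyenv())
.grid_neighbors <- function(smp) {
  key <- paste0("n", smp$n_axial, "x", smp$n_angular, "d", smp$n_disc)
  got <- .nb_cache[[key]]
  if (!is.null(got)) return(got)
  out <- .grid_neighbors_build(smp)
  .nb_cache[[key]] <- out
  out
}
.grid_neighbors_build <- function(smp) {
  na <- smp$n_axial; ng <- smp$n_angular; nd <- smp$n_disc
  nt <- na * ng
  out <- vector("list", nt + nd)
  idx <- function(i, j) (j - 1L) * na + i  # axial fastest, matches expand.grid
  for (j in seq_len(ng)) {
    jm <- if (j == 1L) ng else j - 1L
    jp <- if (j == ng) 1L else j + 1L
    for (i in seq_len(na)) {
      nb <- c(idx(i, jm), idx(i, jp))
      if (i > 1L) nb <- c(nb, idx(i - 1L, j))
      if (i < na) nb <- c(nb, idx(i + 1L, j))
      out[[idx(i, j)]] <- nb
    }
  }
  for (d in seq_len(nd)) {
    # two neighbours on each side: a median over four keeps a single
    # deviant from contaminating its neighbours' statistics
    nb <- ((d - 1L) + c(-2L, -1L, 1L, 2L)) %% nd + 1L
    out[[nt + d]] <- nt + unique(nb[nb != d])
  }
  out
}

#' Detect and tabulate edges for one frame (debugging aid)
#'
#' Runs the full edge-measurement chain (profile extraction, step/peak fit,
#' outlier rejection, variance normalization) for a given model state on one
#' volume and returns the per-sample table, suitable for CSV export.
#'
#' @param vol A `volume3d`.
#' @param mesh A `ds_mesh`.
#' @param x Full state vector `[x_g; x_l]` (length 7 + control points).
#' @param config An [edge_config()].
#' @return Data frame with sample type, image-space position, normal, fitted
#'   displacement `v` (mm), raw `residual`, normalized variance `r` (NA for
#'   rejected edges) and `accepted`.
#' @export
detect_edges_frame <- function(vol, mesh, x, config = edge_config()) {
  n_l <- nrow(mesh$points)
  smp <- sample_surface(mesh, x_l = x[8:(7 + n_l)])
  gmap <- .transform_samples(x[1:7], smp, mesh$dirs, with_local = TRUE)
  prof <- extract_profiles(vol, gmap$p_g, gmap$n_g, config)
  ed <- fit_edges(prof, config)
  cfg <- config
  if (is.null(cfg$min_step_height))
    cfg$min_step_height <- 0.1 * .robust_range(vol)
  ed <- reject_outliers(ed, .grid_neighbors(smp), cfg)
  r <- rep(NA_real_, nrow(ed))
  r[ed$ok] <- normalize_variances(ed$residual[ed$ok], config$r_edge)
  data.frame(type = smp$type,
             x = gmap$p_g[, 1], y = gmap$p_g[, 2], z = gmap$p_g[, 3],
             nx = gmap$n_g[, 1], ny = gmap$n_g[, 2], nz = gmap$n_g[, 3],
             v = ed$v, residual = ed$residual, r = r, accepted = ed$ok)
}

# Full edge measurement pass for one frame: profiles, fits, rejection,
# variance normalization. Returns accepted H rows, displacements and
# variances plus diagnostics.
.measure_edges <- function(vol, smp, gmap, config, h_min) {
  prof <- extract_profiles(vol, gmap$p_g, gmap$n_g, config)
  ed <- fit_edges(prof, config)
  cfg <- config
  cfg$min_step_height <- h_min
  ed <- reject_outliers(ed, .grid_neighbors(smp), cfg)
  acc <- which(ed$ok)
  r <- normalize_variances(ed$residual[acc], config$r_edge)
  list(H = gmap$H[acc, , drop = FALSE], v = ed$v[acc], r = r,
       n_accepted = length(acc), n_total = nrow(ed),
       mean_abs_v = if (length(acc)) mean(abs(ed$v[acc])) else NA_real_)
}
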