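# Shared fixtures: small phantoms are generated once per test run and cached
# so several test files can reuse them without re-rendering volumes.

.fixture_env <- new.env()

fixture_phantom <- function(name = c("clean_static", "moving"), seed = 1L) {
  name <- match.arg(name)
  key <- paste0(name, "_", seed)
  got <- .fixture_env[[key]]
  if (!is.null(got)) return(got)
  cfg <- switch(name,
    clean_static = phantom_config(speckle_level = 0, translation_amp = 0,
                                  rotation_amp_deg = 0),
    moving = phantom_config())
  out <- generate_phantom(cfg, seed = seed)
  .fixture_env[[key]] <- out
  out
}

fixture_fit <- function(name = c("clean_static", "moving"), seed = 1L) {
  name <- match.arg(name)
  key <- paste0("fit_", name, "_", seed)
  got <- .fixture_env[[key]]
  if (!is.null(got)) return(got)
  ph <- fixture_phantom(name, seed)
  out <- fit_annulus(ph$sequence, annulus_init())
  .fixture_env[[key]] <- out
  out
}

# analytic half-space test volume: I = 100 * (x > x0)
halfspace_volume <- function(x0 = 0, n = 41L, spacing = 1) {
  half <- (n - 1) / 2 * spacing
  ax <- seq(-half, half, by = spacing)
  arr <- array(rep(100 * (ax > x0), times = n * n), c(n, n, n))
  volume3d(arr, spacing = rep(spacing, 3), origin = rep(-half, 3))
}

# synthetic profile list compatible with fit_edges()
make_profiles <- function(X, search_mm) {
  list(intensities = X, offsets = seq(-search_mm, search_mm, length.out = ncol(X)),
       usable = rep(TRUE, nrow(X)))
}
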