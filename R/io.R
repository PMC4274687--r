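# Volume-sequence I/O (NIfTI), mesh export (legacy ASCII VTK polydata, OBJ),
# state/result serialization (JSON, CSV, YAML configs). World coordinates
# are mm in an RAS-like frame taken from the NIfTI affine (positive-diagonal
# affines are written; voxel indices are 1-based in R, 0-based on disk).

#' Read a volume sequence
#'
#' Accepts a 4D NIfTI file, or a directory of per-frame 3D NIfTI files
#' (frames in filename-sorted order). Intensities are kept as stored.
#'
#' @param path File or directory path.
#' @param frame_rate Volumes per second (used when the file carries no
#'   time spacing; default 10).
#' @return A [volume_sequence()].
#' @export
read_sequence <- function(path, frame_rate = 10) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (length(files) == 0) stop("no NIfTI files found in ", path)
    imgs <- lapply(files, RNifti::readNifti)
    d1 <- dim(imgs[[1]])
    for (i in seq_along(imgs)) {
      if (!identical(dim(imgs[[i]]), d1))
        stop("inconsistent frame shape in '", basename(files[i]), "': ",
             paste(dim(imgs[[i]]), collapse = "x"), " vs ", paste(d1, collapse = "x"))
    }
    geo <- .nifti_geometry(imgs[[1]])
    frames <- lapply(imgs, function(im) array(as.numeric(im), d1))
    return(volume_sequence(frames, spacing = geo$spacing, origin = geo$origin,
                           frame_rate = frame_rate))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("expected a 3D or 4D NIfTI volume, got ", length(d), "D")
  geo <- .nifti_geometry(img)
  arr <- array(as.numeric(img), d)
  frames <- lapply(seq_len(d[4]), function(k) arr[, , , k])
  dt <- RNifti::pixdim(img)
  dt <- if (length(dt) >= 4 && is.finite(dt[4]) && dt[4] > 0) dt[4] else 1 / frame_rate
  volume_sequence(frames, spacing = geo$spacing, origin = geo$origin,
                  frame_times = (seq_len(d[4]) - 1) * dt)
}

.nifti_geometry <- function(img) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    sp <- sqrt(colSums(unclass(xf)[1:3, 1:3]^2))
    if (all(is.finite(sp)) && all(sp > 0))
      return(list(spacing = sp, origin = unclass(xf)[1:3, 4]))
  }
  pd <- RNifti::pixdim(img)
  list(spacing = pd[1:3], origin = c(0, 0, 0))
}

#' Write a volume sequence as a 4D NIfTI file
#'
#' @param seq A [volume_sequence()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  d <- dim(seq$frames[[1]])
  arr <- array(0, c(d, length(seq$frames)))
  for (k in seq_along(seq$frames)) arr[, , , k] <- seq$frames[[k]]
  img <- RNifti::asNifti(arr)
  dt <- if (length(seq$frame_times) > 1) diff(seq$frame_times)[1] else 1
  RNifti::pixdim(img) <- c(seq$spacing, dt)
  q <- diag(c(seq$spacing, 1))
  q[1:3, 4] <- seq$origin
  img <- RNifti::`qform<-`(img, structure(q, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a surface mesh as legacy ASCII VTK polydata
#'
#' @param vertices n x 3 vertex matrix (mm).
#' @param faces Polygon index matrix (1-based; quads or triangles).
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "surface", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(vertices), "float")), con)
  writeLines(apply(format(vertices, digits = 9, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  nf <- nrow(faces); nv <- ncol(faces)
  writeLines(paste("POLYGONS", nf, nf * (nv + 1)), con)
  writeLines(apply(cbind(nv, faces - 1L), 1, paste, collapse = " "), con)
  invisible(path)
}

#' Export a surface mesh as Wavefront OBJ
#'
#' @inheritParams write_vtk
#' @param path Output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", apply(format(vertices, digits = 9, trim = TRUE,
                                     scientific = FALSE), 1, paste, collapse = " ")), con)
  writeLines(paste("f", apply(faces, 1, paste, collapse = " ")), con)
  invisible(path)
}

#' Write segmentation results to a directory
#'
#' Writes `annulus.csv` (per-frame measures), `summary.json` (status,
#' mid-systolic measures, config echo, package version, seed), per-frame
#' surface meshes under `meshes/`, and `manifest.json` listing all outputs.
#'
#' @param fit An `annulus_fit`.
#' @param outdir Output directory (created if needed).
#' @param seed Seed to echo into the summary (optional).
#' @param meshes Write per-frame VTK meshes (default `TRUE`).
#' @return Character vector of written paths (the manifest), invisibly.
#' @export
write_results <- function(fit, outdir, seed = NULL, meshes = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summary_path <- file.path(outdir, "summary.json")
  if (fit$status != "ok") {
    jsonlite::write_json(list(status = "failed", message = fit$message,
                              version = as.character(utils::packageVersion("annulusEKF")),
                              seed = seed),
                         summary_path, auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(list(outputs = "summary.json"),
                         file.path(outdir, "manifest.json"), auto_unbox = TRUE)
    return(invisible(summary_path))
  }
  csv_path <- file.path(outdir, "annulus.csv")
  utils::write.csv(fit$frames, csv_path, row.names = FALSE)
  paths <- c(paths, csv_path)
  ms <- fit$mid_systole
  row <- fit$frames[ms, ]
  jsonlite::write_json(list(
    status = "ok", mid_systole = ms,
    perimeter_derived_d = row$perimeter_derived_d,
    area_derived_d = row$area_derived_d,
    major_d = row$major_d, minor_d = row$minor_d,
    area = row$area, perimeter = row$perimeter,
    init = unclass(fit$init),
    version = as.character(utils::packageVersion("annulusEKF")),
    seed = seed), summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, summary_path)
  if (meshes) {
    mdir <- file.path(outdir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    surf <- predict(fit, what = "surface")
    for (k in seq_along(surf)) {
      p <- file.path(mdir, sprintf("frame_%02d.vtk", k))
      write_vtk(surf[[k]]$vertices, surf[[k]]$faces, p)
      paths <- c(paths, p)
    }
  }
  manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(list(outputs = basename(paths)), manifest, auto_unbox = TRUE)
  paths <- c(paths, manifest)
  invisible(paths)
}

#' Serialize states or configs to JSON / read them back
#'
#' @param x A list-like object (states, init or phase config).
#' @param path JSON file path.
#' @return `read_state_json` returns the parsed list.
#' @export
write_state_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_state_json
#' @export
read_state_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Load a run configuration from YAML
#'
#' Reads a YAML file with optional sections `init`, `stiff`, `deformable`,
#' `edges_stiff`, `edges_deform` and `phantom`, and materializes the
#' corresponding configuration objects (unspecified entries keep package
#' defaults).
#'
#' @param path YAML file path.
#' @return List with `init`, `control` and (if present) `phantom`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, args) do.call(fun, args %||% list())
  edges_s <- build(edge_config, y$edges_stiff)
  edges_d <- if (!is.null(y$edges_deform)) build(edge_config, y$edges_deform)
             else edge_config(search_mm = 7, n_samples = 15L)
  stiff_args <- y$stiff %||% list(); stiff_args$edges <- edges_s
  def_args <- y$deformable %||% list(A_translation = 0.98, A_scale = 0.98, A_rotation = 0.98)
  def_args$edges <- edges_d
  list(init = build(annulus_init, y$init),
       control = annulus_control(stiff = build(phase_config, stiff_args),
                                 deformable = build(phase_config, def_args)),
       phantom = if (!is.null(y$phantom)) build(phantom_config, y$phantom) else NULL)
}
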