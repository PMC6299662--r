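# On-disk dialect: tabular payloads as plain CSV, everything that is not a
# rectangle (axes, acquisition parameters, provenance, seeds) in a JSON
# sidecar next to the CSV, named <stem>.json. format_version bumps on any
# schema change.
.format_version <- "1.0"

.sidecar_path <- function(path) sub("\\.csv$", ".json", path)

.clean_provenance <- function(p) {
  p$longitudinal <- NULL           # bulky diagnostic array, not serialized
  p
}

# jsonlite drops the names of named atomic vectors; keep metabolite->ppm
# and similar maps as JSON objects
.serialize_acq <- function(acq) {
  if (is.null(acq)) return(NULL)
  a <- unclass(acq)
  a$peak_ppm <- as.list(a$peak_ppm)
  a
}

#' Write / read a dynamic series (CSV + JSON sidecar)
#'
#' The CSV has a `time_s` column followed by one column per metabolite; the
#' sidecar records the acquisition parameters, low-confidence flags and
#' provenance.
#'
#' @param series a [dynamic_series()]
#' @param path CSV path (`.csv`); the sidecar goes to the same stem `.json`
#' @return `write_dynamic_series` the path, invisibly;
#'   `read_dynamic_series` a [dynamic_series()]
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  df <- data.frame(time_s = series$time_axis, series$intensities,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(format_version = .format_version, kind = "dynamic_series",
               acquisition = .serialize_acq(series$acquisition),
               flags = series$flags,
               provenance = .clean_provenance(series$provenance))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  acq <- if (!is.null(meta$acquisition))
    do.call(acquisition_params, meta$acquisition[
      c("flip_angle", "tr", "n_timepoints", "ppm_axis", "linewidth",
        "peak_ppm")])
  flags <- if (!is.null(meta$flags)) lapply(meta$flags, as.logical)
  dynamic_series(df$time_s, as.list(df[setdiff(names(df), "time_s")]),
                 acquisition = acq, flags = flags,
                 provenance = as.list(meta$provenance))
}

#' Write / read a spectral matrix (CSV + JSON sidecar)
#'
#' Rows are timepoints; the first column is `time_s`, the remaining columns
#' the ppm bins. The ppm axis and provenance live in the sidecar.
#'
#' @param spec a [spectral_matrix()]
#' @param path CSV path
#' @return the path invisibly / a [spectral_matrix()]
#' @export
write_spectral_matrix <- function(spec, path) {
  stopifnot(inherits(spec, "spectral_matrix"))
  df <- data.frame(time_s = spec$time_axis, spec$data, check.names = FALSE)
  names(df) <- c("time_s", sprintf("ppm_%g", spec$ppm_axis))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(format_version = .format_version, kind = "spectral_matrix",
               ppm_axis = spec$ppm_axis,
               provenance = .clean_provenance(spec$provenance))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectral_matrix
#' @export
read_spectral_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  data <- as.matrix(df[setdiff(names(df), "time_s")])
  dimnames(data) <- NULL
  spectral_matrix(data, meta$ppm_axis, df$time_s,
                  provenance = as.list(meta$provenance))
}

#' Write / read a CSI spectra grid as a plain-text container
#'
#' A directory holding `spectra.csv` (one row per voxel, `row`/`col` 0-based
#' indices followed by the ppm bins), `masks.csv` (one 0/1 column per mask)
#' and `meta.json` (ppm axis, geometry, provenance). Voxel order is
#' row-major.
#'
#' @param grid a [spectra_grid()]
#' @param dir container directory (created if needed)
#' @return the directory invisibly / a [spectra_grid()]
#' @export
write_spectra_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "spectra_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(grid$spectra)
  ij <- expand.grid(col = seq_len(d[2]), row = seq_len(d[1]))[, 2:1]
  flat <- t(apply(ij, 1, function(v) grid$spectra[v[1], v[2], ]))
  df <- data.frame(row = ij$row - 1L, col = ij$col - 1L, flat,
                   check.names = FALSE)
  names(df) <- c("row", "col", sprintf("ppm_%g", grid$ppm_axis))
  utils::write.csv(df, file.path(dir, "spectra.csv"), row.names = FALSE)
  if (length(grid$masks)) {
    mdf <- data.frame(row = ij$row - 1L, col = ij$col - 1L)
    for (nm in names(grid$masks))
      mdf[[nm]] <- as.integer(grid$masks[[nm]][as.matrix(ij)])
    utils::write.csv(mdf, file.path(dir, "masks.csv"), row.names = FALSE)
  }
  meta <- list(format_version = .format_version, kind = "spectra_grid",
               ppm_axis = grid$ppm_axis, geometry = grid$geometry,
               provenance = .clean_provenance(grid$provenance))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_spectra_grid
#' @export
read_spectra_grid <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "spectra.csv"), check.names = FALSE)
  nr <- max(df$row) + 1L; nc <- max(df$col) + 1L
  n_ppm <- length(meta$ppm_axis)
  spectra <- array(0, c(nr, nc, n_ppm))
  vals <- as.matrix(df[-(1:2)])
  for (i in seq_len(nrow(df)))
    spectra[df$row[i] + 1L, df$col[i] + 1L, ] <- vals[i, ]
  masks <- list()
  mask_path <- file.path(dir, "masks.csv")
  if (file.exists(mask_path)) {
    mdf <- utils::read.csv(mask_path, check.names = FALSE)
    for (nm in setdiff(names(mdf), c("row", "col"))) {
      m <- matrix(FALSE, nr, nc)
      m[cbind(mdf$row + 1L, mdf$col + 1L)] <- mdf[[nm]] == 1L
      masks[[nm]] <- m
    }
  }
  spectra_grid(spectra, meta$ppm_axis, meta$geometry$fov,
               meta$geometry$slice_thickness, masks,
               provenance = as.list(meta$provenance))
}

#' Export a metabolite map as NIfTI
#'
#' Writes the map as a single-slice NIfTI volume with voxel dimensions taken
#' from the acquisition geometry (in-plane resolution and slice thickness),
#' for overlay in standard viewers. Invalid voxels are written as NA.
#' Requires the RNifti package.
#'
#' @param map a `metabolite_map`
#' @param path output path (`.nii` or `.nii.gz`)
#' @return the path, invisibly
#' @export
write_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "metabolite_map"))
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export", call. = FALSE)
  vol <- array(map$values, c(dim(map$values), 1L))
  vol[array(!map$valid, dim(vol))] <- NA_real_
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(map$geometry$resolution,
                           map$geometry$slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}
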