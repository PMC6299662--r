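#' Dynamic per-metabolite peak-intensity series
#'
#' Container for one injection's time-resolved metabolite signals: a common
#' time axis in seconds and one nonnegative intensity series per metabolite.
#'
#' @param time_axis sampling times in seconds, strictly increasing
#' @param intensities named list of numeric vectors, one per metabolite,
#'   all the same length as `time_axis`
#' @param acquisition the `acq_params` the series was acquired/simulated with
#' @param flags optional named list of logical vectors marking low-confidence
#'   points per metabolite
#' @param provenance free-form metadata list (seed, generator parameters, ...)
#' @return an object of class `dynamic_series`
#' @export
dynamic_series <- function(time_axis, intensities, acquisition = NULL,
                           flags = NULL, provenance = list()) {
  time_axis <- as.numeric(time_axis)
  if (any(diff(time_axis) <= 0))
    stop("time_axis must be strictly increasing", call. = FALSE)
  if (!length(intensities) || is.null(names(intensities)))
    stop("intensities must be a named list of series", call. = FALSE)
  lens <- vapply(intensities, length, integer(1))
  if (any(lens != length(time_axis)))
    stop("every intensity series must match time_axis length", call. = FALSE)
  structure(list(time_axis = time_axis,
                 intensities = lapply(intensities, as.numeric),
                 acquisition = acquisition, flags = flags,
                 provenance = provenance),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat("Dynamic series:", length(x$time_axis), "timepoints,",
      paste(names(x$intensities), collapse = ", "), "\n")
  invisible(x)
}

#' Time-resolved spectral matrix (time x ppm)
#'
#' @param data numeric matrix, rows = timepoints, columns = ppm bins
#' @param ppm_axis chemical-shift axis matching `ncol(data)`
#' @param time_axis sampling times in seconds matching `nrow(data)`
#' @param provenance metadata list (acquisition, kinetics, seed, warnings)
#' @return an object of class `spectral_matrix`
#' @export
spectral_matrix <- function(data, ppm_axis, time_axis, provenance = list()) {
  data <- as.matrix(data)
  if (ncol(data) != length(ppm_axis))
    stop("ppm_axis length must equal ncol(data)", call. = FALSE)
  if (nrow(data) != length(time_axis))
    stop("time_axis length must equal nrow(data)", call. = FALSE)
  if (any(diff(as.numeric(time_axis)) <= 0))
    stop("time_axis must be strictly increasing", call. = FALSE)
  structure(list(data = data, ppm_axis = as.numeric(ppm_axis),
                 time_axis = as.numeric(time_axis), provenance = provenance),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat("Spectral matrix:", nrow(x$data), "timepoints x", ncol(x$data),
      "ppm bins\n")
  invisible(x)
}

#' Single-timepoint CSI spectral grid
#'
#' Chemical shift imaging container: one spectrum per voxel on a row x col
#' grid, plus acquisition geometry and named region-of-interest masks.
#' In-plane resolution is derived as FOV / matrix elementwise. Voxel indices
#' are row-major and 0-based in the on-disk schema; in R the natural 1-based
#' matrix indexing is used.
#'
#' @param spectra numeric array `c(nrow, ncol, n_ppm)`
#' @param ppm_axis chemical-shift axis, length `dim(spectra)[3]`
#' @param fov field of view `c(row_mm, col_mm)` in mm
#' @param slice_thickness slice thickness in mm
#' @param masks named list of logical `nrow x ncol` matrices
#' @param provenance metadata list
#' @return an object of class `spectra_grid`; `$geometry$resolution` holds
#'   the derived in-plane resolution in mm
#' @export
spectra_grid <- function(spectra, ppm_axis, fov, slice_thickness = 3.5,
                         masks = list(), provenance = list()) {
  d <- dim(spectra)
  if (length(d) != 3L)
    stop("spectra must be a 3-d array (row x col x ppm)", call. = FALSE)
  if (d[3] != length(ppm_axis))
    stop("ppm_axis length must equal dim(spectra)[3]", call. = FALSE)
  if (length(fov) != 2L || any(fov <= 0))
    stop("fov must be two positive extents in mm", call. = FALSE)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), d[1:2]))
      stop("mask '", nm, "' must be a logical matrix matching the grid shape",
           call. = FALSE)
  }
  geometry <- list(fov = as.numeric(fov), matrix_size = as.integer(d[1:2]),
                   slice_thickness = slice_thickness,
                   resolution = as.numeric(fov) / d[1:2])
  structure(list(spectra = spectra, ppm_axis = as.numeric(ppm_axis),
                 geometry = geometry, masks = masks, provenance = provenance),
            class = "spectra_grid")
}

#' @export
print.spectra_grid <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("CSI grid %dx%d, FOV %gx%g mm, resolution %gx%g mm, %d ppm bins\n",
              g$matrix_size[1], g$matrix_size[2], g$fov[1], g$fov[2],
              g$resolution[1], g$resolution[2], length(x$ppm_axis)))
  if (length(x$masks))
    cat("Masks:", paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}

#' Per-voxel metabolite (or ratio) map with validity mask
#'
#' @param values numeric row x col matrix of peak intensities or ratios
#' @param label metabolite or ratio label
#' @param valid logical matrix marking voxels passing the SNR gate
#' @param geometry geometry list copied from the source grid
#' @return an object of class `metabolite_map`
#' @export
metabolite_map_obj <- function(values, label, valid, geometry) {
  values <- as.matrix(values)
  if (!identical(dim(valid), dim(values)))
    stop("validity mask must match map shape", call. = FALSE)
  structure(list(values = values, label = label, valid = valid,
                 geometry = geometry),
            class = "metabolite_map")
}

#' @export
print.metabolite_map <- function(x, ...) {
  cat(sprintf("Map '%s': %dx%d, %d valid voxels\n", x$label,
              nrow(x$values), ncol(x$values), sum(x$valid)))
  invisible(x)
}
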