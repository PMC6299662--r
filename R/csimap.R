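#' Per-voxel metabolite map from a CSI grid
#'
#' For each voxel, the map value is the maximum magnitude of the voxel
#' spectrum within `window_ppm` of the metabolite's nominal chemical shift.
#' A voxel is valid when its peak exceeds `snr_gate` times the grid's robust
#' noise estimate (median absolute deviation over a signal-free ppm band,
#' i.e. all bins outside every peak window). On an all-zero or pure-noise
#' grid every voxel is invalid.
#'
#' @param grid a [spectra_grid()]
#' @param metabolite metabolite label; must be a name of `acq$peak_ppm`
#' @param acq an [acquisition_params()] carrying the peak table
#' @param window_ppm half-width of the peak search window, ppm
#' @param snr_gate validity gate in noise multiples (default 5)
#' @return a `metabolite_map` (see [metabolite_map_obj()]) with geometry
#'   copied from the grid
#' @export
metabolite_map <- function(grid, metabolite, acq, window_ppm = 2,
                           snr_gate = 5) {
  stopifnot(inherits(grid, "spectra_grid"), inherits(acq, "acq_params"))
  if (!metabolite %in% names(acq$peak_ppm))
    stop("unknown metabolite '", metabolite, "'; known: ",
         paste(names(acq$peak_ppm), collapse = ", "), call. = FALSE)
  ppm <- grid$ppm_axis
  win <- which(abs(ppm - acq$peak_ppm[[metabolite]]) <= window_ppm)
  if (!length(win))
    stop("empty window for ", metabolite, " on this ppm axis", call. = FALSE)
  all_win <- unlist(lapply(acq$peak_ppm, function(p)
    which(abs(ppm - p) <= window_ppm)))
  noise_bins <- setdiff(seq_along(ppm), all_win)
  noise <- if (length(noise_bins))
    stats::mad(as.numeric(grid$spectra[, , noise_bins]), center = 0) else 0

  sub <- abs(grid$spectra[, , win, drop = FALSE])
  values <- apply(sub, c(1, 2), max)
  valid <- values > snr_gate * noise
  metabolite_map_obj(values, metabolite, valid, grid$geometry)
}

#' Lactate/pyruvate (or any) ratio map
#'
#' Elementwise ratio of two congruent metabolite maps, defined on the
#' intersection of their validity masks — in particular a ratio voxel is
#' invalid wherever the denominator failed its SNR gate, so the map cannot
#' blow up at vanishing pyruvate.
#'
#' @param num numerator `metabolite_map` (e.g. lactate)
#' @param den denominator `metabolite_map` (e.g. pyruvate)
#' @return a `metabolite_map` labelled `"num/den"`
#' @export
ratio_map <- function(num, den) {
  stopifnot(inherits(num, "metabolite_map"), inherits(den, "metabolite_map"))
  if (!identical(dim(num$values), dim(den$values)) ||
      !isTRUE(all.equal(num$geometry$fov, den$geometry$fov)) ||
      !identical(num$geometry$matrix_size, den$geometry$matrix_size))
    stop("ratio_map: maps have mismatched geometry", call. = FALSE)
  valid <- num$valid & den$valid
  values <- matrix(NA_real_, nrow(num$values), ncol(num$values))
  values[valid] <- num$values[valid] / den$values[valid]
  metabolite_map_obj(values, paste0(num$label, "/", den$label), valid,
                     num$geometry)
}

#' ROI statistics of a metabolite or ratio map
#'
#' Mean, SD and count over the valid voxels inside a named mask.
#'
#' @param map a `metabolite_map`
#' @param mask logical matrix matching the map, or the name of a mask when
#'   `masks` is supplied
#' @param masks optional named list of masks (e.g. `grid$masks`)
#' @return list `mean`, `sd`, `n_valid`, `n_mask`
#' @export
roi_stats <- function(map, mask, masks = NULL) {
  stopifnot(inherits(map, "metabolite_map"))
  if (is.character(mask)) {
    if (is.null(masks) || !mask %in% names(masks))
      stop("mask '", mask, "' not found", call. = FALSE)
    mask <- masks[[mask]]
  }
  if (!identical(dim(mask), dim(map$values)))
    stop("mask shape does not match the map", call. = FALSE)
  sel <- mask & map$valid
  if (!any(sel))
    stop("no valid voxels inside the mask", call. = FALSE)
  v <- map$values[sel]
  list(mean = mean(v), sd = stats::sd(v), n_valid = length(v),
       n_mask = sum(mask))
}

#' Downsample a CSI grid by voxel averaging
#'
#' Averages `factor x factor` voxel blocks of the spectra (the coarser
#' acquisition matrix alternative, e.g. 18 x 24 down to 9 x 12). FOV is
#' unchanged, so the derived in-plane resolution doubles. Masks keep a
#' coarse voxel when at least half of its fine voxels were in the mask.
#'
#' @param grid a [spectra_grid()]
#' @param factor integer block size (grid dimensions must be divisible)
#' @return a [spectra_grid()] at the coarser matrix
#' @export
downsample_grid <- function(grid, factor = 2) {
  stopifnot(inherits(grid, "spectra_grid"))
  d <- dim(grid$spectra)
  if (any(d[1:2] %% factor != 0))
    stop("grid dimensions not divisible by the downsampling factor",
         call. = FALSE)
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  block_mean <- function(m) {
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc))
      out[i, j] <- mean(m[(i - 1) * factor + seq_len(factor),
                          (j - 1) * factor + seq_len(factor)])
    out
  }
  spectra <- array(0, c(nr, nc, d[3]))
  for (k in seq_len(d[3]))
    spectra[, , k] <- block_mean(grid$spectra[, , k])
  masks <- lapply(grid$masks, function(m) block_mean(m) >= 0.5)
  spectra_grid(spectra, grid$ppm_axis, grid$geometry$fov,
               grid$geometry$slice_thickness, masks,
               provenance = c(grid$provenance,
                              list(downsampled_by = factor)))
}
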