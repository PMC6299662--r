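#' Simulate two-site exchange of hyperpolarized pyruvate
#'
#' Forward model of the dynamic experiment. Longitudinal magnetizations of
#' pyruvate (Mp), lactate (Ml) and optionally bicarbonate (Mb) obey the
#' linear exchange system
#' \deqn{dMp/dt = -(r1p + kp + kb) Mp + kl Ml + u(t)}
#' \deqn{dMl/dt = kp Mp - (r1l + kl) Ml}
#' \deqn{dMb/dt = kb Mp - r1b Mb}
#' with a boxcar bolus input \eqn{u(t)}. At every repetition time an
#' excitation reads out \eqn{sin(\theta) Mz} and multiplies the remaining
#' longitudinal magnetization by \eqn{cos(\theta)} — the non-renewable
#' polarization budget of a hyperpolarized experiment. The system is
#' propagated exactly between excitations with a matrix exponential of the
#' affine (input-augmented) generator, with breakpoints at the bolus edges,
#' so the boxcar input incurs no discretization error.
#'
#' @param kin a [kinetic_params()] object
#' @param acq an [acquisition_params()] object
#' @return a [dynamic_series()] whose intensities are the observed
#'   (transverse, \eqn{\sin\theta\,Mz}) signals at each excitation; the
#'   pre-excitation longitudinal magnetizations are kept in
#'   `provenance$longitudinal` (timepoints x metabolites)
#' @examples
#' ser <- simulate_exchange(kinetic_params(kp = 0.021), acquisition_params())
#' plot(ser$time_axis, ser$intensities$lactate, type = "l")
#' @export
simulate_exchange <- function(kin, acq) {
  stopifnot(inherits(kin, "kinetic_params"), inherits(acq, "acq_params"))
  theta <- acq$flip_angle * pi / 180
  n <- acq$n_timepoints
  t_samp <- (seq_len(n) - 1) * acq$tr

  metabs <- c("pyruvate", "lactate", "bicarbonate")
  mz <- matrix(0, n, 3, dimnames = list(NULL, metabs))
  x <- c(0, 0, 0)
  cache <- new.env(parent = emptyenv())

  mz[1, ] <- x
  for (k in seq_len(n - 1)) {
    x <- x * cos(theta)                      # depletion by excitation k
    x <- .propagate_exchange(x, t_samp[k], t_samp[k + 1], kin, cache)
    if (any(!is.finite(x)))
      stop("non-finite magnetization during integration; check rate ",
           "parameters (kp/kl/kb/r1p/r1l/r1b)", call. = FALSE)
    mz[k + 1, ] <- x
  }
  mz[mz < 0 & mz > -1e-12] <- 0              # numerical dust only

  keep <- c("pyruvate", "lactate", if (kin$kb > 0) "bicarbonate")
  intensities <- lapply(keep, function(m) sin(theta) * mz[, m])
  names(intensities) <- keep
  dynamic_series(t_samp, intensities, acquisition = acq,
                 provenance = list(kinetics = unclass(kin),
                                   longitudinal = mz,
                                   generator = "simulate_exchange"))
}

# Exact propagation of the affine system x' = A x + b over [t0, t1],
# splitting at the bolus edges so the input is piecewise constant.
.propagate_exchange <- function(x, t0, t1, kin, cache) {
  edges <- sort(unique(c(t0, t1,
                         kin$bolus_start, kin$bolus_start + kin$bolus_duration)))
  edges <- edges[edges >= t0 & edges <= t1]
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    dt <- b - a
    if (dt <= 0) next
    on <- (a >= kin$bolus_start) &&
      (b <= kin$bolus_start + kin$bolus_duration)
    u <- if (on) kin$bolus_amplitude else 0
    key <- paste0(format(dt, digits = 17), "|", u)
    P <- cache[[key]]
    if (is.null(P)) {
      A <- matrix(c(-(kin$r1p + kin$kp + kin$kb), kin$kl,             0, u,
                    kin$kp,                     -(kin$r1l + kin$kl),  0, 0,
                    kin$kb,                      0,            -kin$r1b, 0,
                    0,                           0,                   0, 0),
                  4, 4, byrow = TRUE)
      P <- pracma::expm(A * dt)
      cache[[key]] <- P
    }
    x <- (P %*% c(x, 1))[1:3]
  }
  x
}

# Unit-height Lorentzian lineshape (peak value 1 at center), fwhm in ppm.
.lorentz <- function(ppm, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((ppm - center)^2 + hw2)
}

#' Synthesize a spectral matrix from metabolite time courses
#'
#' Builds one spectrum per timepoint as a sum of Lorentzian resonances at the
#' nominal chemical shifts, each with peak height equal to that timepoint's
#' metabolite intensity, plus iid Gaussian noise. Peaks closer together than
#' twice the linewidth are recorded as an overlap warning in the provenance
#' metadata (the synthesis still proceeds).
#'
#' @param series a [dynamic_series()] with one series per metabolite
#' @param acq an [acquisition_params()]; only metabolites present in both
#'   `series$intensities` and `acq$peak_ppm` are synthesized
#' @param noise_sd standard deviation of additive Gaussian noise, signal units
#' @param seed integer seed for the noise draw (required when `noise_sd > 0`);
#'   the global RNG state is left untouched
#' @return a [spectral_matrix()]
#' @export
synthesize_spectra <- function(series, acq, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(series, "dynamic_series"), inherits(acq, "acq_params"))
  metabs <- intersect(names(series$intensities), names(acq$peak_ppm))
  if (!length(metabs))
    stop("no metabolite in the series matches acq$peak_ppm", call. = FALSE)
  n_t <- length(series$time_axis)

  warnings <- character(0)
  pos <- acq$peak_ppm[metabs]
  if (length(pos) > 1) {
    d <- abs(outer(pos, pos, "-"))
    close <- which(d < 2 * acq$linewidth & upper.tri(d), arr.ind = TRUE)
    if (nrow(close))
      warnings <- sprintf("peak overlap: %s and %s closer than 2x linewidth",
                          metabs[close[, 1]], metabs[close[, 2]])
  }

  shapes <- vapply(metabs, function(m)
    .lorentz(acq$ppm_axis, acq$peak_ppm[[m]], acq$linewidth),
    numeric(length(acq$ppm_axis)))
  heights <- do.call(cbind, series$intensities[metabs])
  data <- heights %*% t(shapes)

  if (noise_sd > 0) {
    if (is.null(seed))
      stop("a seed is required when noise_sd > 0", call. = FALSE)
    noise <- withr::with_seed(as.integer(seed),
                              matrix(stats::rnorm(length(data), 0, noise_sd),
                                     nrow(data), ncol(data)))
    data <- data + noise
  }
  spectral_matrix(data, acq$ppm_axis, series$time_axis,
                  provenance = list(noise_sd = noise_sd, seed = seed,
                                    warnings = warnings,
                                    source = series$provenance))
}

#' Elliptical brain phantom masks for a CSI grid
#'
#' Generates named logical masks on an `nrow x ncol` grid emulating a mouse
#' brain slice: disjoint kinetic regions (`cortex`, `hippocampus`, `striatum`,
#' `vascular`) plus composite ROI masks (`whole_brain` = the three
#' parenchymal regions, `mtl` = a medial temporal band containing the
#' hippocampus). Shapes are defined in normalized coordinates so the phantom
#' scales with the matrix size.
#'
#' @param nrow,ncol grid dimensions (default the 18 x 24 CSI matrix)
#' @return named list of logical matrices
#' @export
csi_phantom_masks <- function(nrow = 18, ncol = 24) {
  r <- (row(matrix(0, nrow, ncol)) - 0.5) / nrow   # normalized center coords
  c_ <- (col(matrix(0, nrow, ncol)) - 0.5) / ncol
  ell <- function(r0, c0, ar, ac) ((r - r0) / ar)^2 + ((c_ - c0) / ac)^2 <= 1

  brain <- ell(0.5, 0.5, 0.38, 0.40)
  hippo <- ell(0.42, 0.35, 0.10, 0.08) | ell(0.42, 0.65, 0.10, 0.08)
  stria <- ell(0.62, 0.42, 0.09, 0.07) | ell(0.62, 0.58, 0.09, 0.07)
  vascular <- ell(0.5, 0.5, 0.46, 0.48) & !ell(0.5, 0.5, 0.40, 0.42)
  hippo <- hippo & brain
  stria <- stria & brain & !hippo
  cortex <- brain & !hippo & !stria
  vascular <- vascular & !brain
  mtl <- (ell(0.45, 0.5, 0.22, 0.35) & brain) | hippo
  list(cortex = cortex, hippocampus = hippo, striatum = stria,
       vascular = vascular, whole_brain = brain, mtl = mtl)
}

#' Simulate a single-timepoint CSI spectral grid
#'
#' Each voxel belongs to at most one kinetic region; its metabolite signals
#' are the longitudinal magnetizations of the exchange model evolved (without
#' intermediate excitations) from injection to the acquisition delay, read
#' out once with the acquisition flip angle, and rendered as Lorentzian
#' resonances plus Gaussian noise. Voxels outside every region stay at the
#' noise floor. Geometry metadata records FOV, matrix size, slice thickness
#' and the derived in-plane resolution.
#'
#' @param region_kinetics named list of [kinetic_params()], one per kinetic
#'   region; names must match entries of `masks`
#' @param acq an [acquisition_params()]
#' @param masks named list of logical matrices (regions must be disjoint);
#'   extra masks (composite ROIs) are carried through to the container
#' @param fov field of view `c(row_mm, col_mm)`, default 18 x 24 mm
#' @param slice_thickness slice thickness in mm
#' @param acq_delay seconds between injection and CSI readout
#' @param noise_sd spectral noise SD; `seed` required when positive
#' @param seed integer seed for the noise draw
#' @return a [spectra_grid()]; per-region ground-truth signal amplitudes are
#'   stored in `provenance$region_truth`
#' @export
simulate_csi <- function(region_kinetics, acq, masks = csi_phantom_masks(),
                         fov = c(18, 24), slice_thickness = 3.5,
                         acq_delay = 18, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(acq, "acq_params"))
  if (!length(region_kinetics) || is.null(names(region_kinetics)))
    stop("region_kinetics must be a named list of kinetic_params", call. = FALSE)
  missing_masks <- setdiff(names(region_kinetics), names(masks))
  if (length(missing_masks))
    stop("no mask for region(s): ", paste(missing_masks, collapse = ", "),
         call. = FALSE)
  shape <- dim(masks[[1]])
  for (nm in names(masks))
    if (!identical(dim(masks[[nm]]), shape))
      stop("mask '", nm, "' shape does not match the grid", call. = FALSE)
  reg <- names(region_kinetics)
  if (length(reg) > 1) {
    overlap <- Reduce(`+`, lapply(masks[reg], function(m) m * 1L))
    if (any(overlap > 1L))
      stop("kinetic region masks overlap; regions must be disjoint",
           call. = FALSE)
  }

  theta <- acq$flip_angle * pi / 180
  # region ground truth: Mz at the acquisition delay, one undisturbed
  # evolution (no excitations during the delay), single readout sin(theta)*Mz
  truth <- lapply(region_kinetics, function(kin) {
    stopifnot(inherits(kin, "kinetic_params"))
    cache <- new.env(parent = emptyenv())
    x <- .propagate_exchange(c(0, 0, 0), 0, acq_delay, kin, cache)
    if (any(!is.finite(x)))
      stop("non-finite magnetization during CSI integration; check rates",
           call. = FALSE)
    sin(theta) * pmax(x, 0)
  })

  metabs <- c("pyruvate", "lactate", "bicarbonate")
  metabs <- intersect(metabs, names(acq$peak_ppm))
  shapes <- vapply(metabs, function(m)
    .lorentz(acq$ppm_axis, acq$peak_ppm[[m]], acq$linewidth),
    numeric(length(acq$ppm_axis)))

  n_ppm <- length(acq$ppm_axis)
  spectra <- array(0, c(shape[1], shape[2], n_ppm))
  idx <- c(pyruvate = 1L, lactate = 2L, bicarbonate = 3L)
  for (rg in reg) {
    h <- truth[[rg]][idx[metabs]]
    spec <- as.numeric(shapes %*% h)
    vox <- which(masks[[rg]], arr.ind = TRUE)
    for (j in seq_len(nrow(vox)))
      spectra[vox[j, 1], vox[j, 2], ] <- spec
  }
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("a seed is required when noise_sd > 0", call. = FALSE)
    spectra <- spectra + withr::with_seed(as.integer(seed),
      array(stats::rnorm(length(spectra), 0, noise_sd), dim(spectra)))
  }
  region_truth <- do.call(rbind, lapply(truth, function(x)
    stats::setNames(x, c("pyruvate", "lactate", "bicarbonate"))))
  spectra_grid(spectra, acq$ppm_axis, fov, slice_thickness, masks,
               provenance = list(acq_delay = acq_delay, noise_sd = noise_sd,
                                 seed = seed, region_truth = region_truth))
}

#' Simulate a two-group cohort with known ground truth
#'
#' Draws per-subject forward rate constants from each group's normal
#' distribution (truncated at 0) and per-subject perfusion scales multiplying
#' the bolus amplitude, simulates every subject's noiseless dynamic series
#' with [simulate_exchange()], and builds a ground-truth table including a
#' behavior score generated from the linear model
#' `target_time = intercept - slope * ratio + noise`, where `ratio` is the
#' subject's noiseless mean lactate/pyruvate ratio. Object-location
#' exploration times (`t_novel`, `t_familiar`) are generated from a latent
#' discrimination index tied to the same ratio. All draws flow from
#' `spec$seed`; the global RNG state is untouched.
#'
#' @param spec a [cohort_spec()]
#' @param acq an [acquisition_params()] shared by all subjects
#' @return list with `subjects` (named list of [dynamic_series()]) and
#'   `truth` (data.frame: subject_id, group, kp_true, perfusion_true,
#'   ratio_true, target_time, t_novel, t_familiar, spectra_seed)
#' @export
simulate_cohort <- function(spec, acq = acquisition_params()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(acq, "acq_params"))
  n <- spec$n_per_group
  draws <- withr::with_seed(spec$seed, {
    kp <- perf <- numeric(2 * n)
    for (g in 1:2) {
      i <- (g - 1) * n + seq_len(n)
      kp[i] <- .rtrunc_norm(n, spec$group_kp_mean[g], spec$group_kp_sd[g], 0)
      perf[i] <- .rtrunc_norm(n, spec$perfusion_mean[g], spec$perfusion_sd[g],
                              0.01)
    }
    list(kp = kp, perf = perf,
         beh_noise = stats::rnorm(2 * n, 0, spec$behavior_sd),
         di_noise = stats::rnorm(2 * n, 0, 0.08),
         spectra_seed = sample.int(.Machine$integer.max, 2 * n))
  })

  ids <- sprintf("%s_%02d", rep(spec$group_names, each = n), rep(seq_len(n), 2))
  subjects <- vector("list", 2 * n)
  names(subjects) <- ids
  ratio_true <- numeric(2 * n)
  for (i in seq_len(2 * n)) {
    kin <- kinetic_params(kp = draws$kp[i], kb = spec$kb,
                          bolus_amplitude = draws$perf[i])
    ser <- simulate_exchange(kin, acq)
    subjects[[i]] <- ser
    p <- ser$intensities$pyruvate
    valid <- p > 0.05 * max(p)
    ratio_true[i] <- mean(ser$intensities$lactate[valid] / p[valid])
  }

  target_time <- spec$behavior_intercept -
    spec$behavior_slope * ratio_true + draws$beh_noise
  di_latent <- pmin(0.9, pmax(-0.9, 0.55 - 1.4 * ratio_true + draws$di_noise))
  t_total <- 40
  truth <- data.frame(
    subject_id = ids,
    group = rep(spec$group_names, each = n),
    kp_true = draws$kp,
    perfusion_true = draws$perf,
    ratio_true = ratio_true,
    target_time = target_time,
    t_novel = t_total * (1 + di_latent) / 2,
    t_familiar = t_total * (1 - di_latent) / 2,
    spectra_seed = draws$spectra_seed,
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, truth = truth)
}

# normal draw truncated below at `lo` (rejection; sd = 0 degenerates to mean)
.rtrunc_norm <- function(n, mean, sd, lo) {
  if (sd == 0) return(rep(pmax(mean, lo), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- stats::rnorm(1, mean, sd)
    while (x < lo) x <- stats::rnorm(1, mean, sd)
    out[i] <- x
  }
  out
}
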