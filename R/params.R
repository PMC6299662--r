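#' Acquisition parameters for a dynamic hyperpolarized 13C experiment
#'
#' Describes the pulse sequence and the spectral axis: a pulse-and-acquire
#' scheme with a constant flip angle, repetition time `tr`, `n_timepoints`
#' excitations, and a chemical-shift (ppm) axis on which Lorentzian resonances
#' are placed. Defaults follow a typical small-animal protocol: 10 degree
#' excitation every 1 s for 90 s, with [1-13C]pyruvate at 173 ppm,
#' [1-13C]lactate at 185 ppm and 13C-bicarbonate near 161 ppm. The default
#' 0.4 ppm FWHM corresponds to about 40 Hz at a 9.4 T carbon frequency,
#' typical of in vivo 13C linewidths.
#'
#' @param flip_angle excitation flip angle in degrees, in (0, 90)
#' @param tr repetition time in seconds (> 0)
#' @param n_timepoints number of excitations / sampled spectra (>= 2)
#' @param ppm_axis strictly increasing chemical-shift grid in ppm
#' @param linewidth Lorentzian full width at half maximum in ppm
#' @param peak_ppm named numeric vector mapping metabolite to chemical shift;
#'   every value must lie inside the range of `ppm_axis`
#' @return an object of class `acq_params`
#' @examples
#' acq <- acquisition_params()
#' acq$peak_ppm[["pyruvate"]]
#' @export
acquisition_params <- function(flip_angle = 10,
                               tr = 1,
                               n_timepoints = 90,
                               ppm_axis = seq(150, 200, by = 0.2),
                               linewidth = 0.4,
                               peak_ppm = c(pyruvate = 173, lactate = 185,
                                            bicarbonate = 161)) {
  stopifnot(is.numeric(flip_angle), length(flip_angle) == 1L,
            is.numeric(tr), length(tr) == 1L,
            is.numeric(n_timepoints), length(n_timepoints) == 1L)
  if (!is.finite(flip_angle) || flip_angle <= 0 || flip_angle >= 90)
    stop("flip_angle must lie strictly between 0 and 90 degrees", call. = FALSE)
  if (!is.finite(tr) || tr <= 0)
    stop("tr must be a positive number of seconds", call. = FALSE)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 2L)
    stop("n_timepoints must be at least 2", call. = FALSE)
  ppm_axis <- as.numeric(ppm_axis)
  if (length(ppm_axis) < 2L || any(!is.finite(ppm_axis)) ||
      any(diff(ppm_axis) <= 0))
    stop("ppm_axis must be a strictly increasing finite grid", call. = FALSE)
  if (!is.finite(linewidth) || linewidth <= 0)
    stop("linewidth must be a positive FWHM in ppm", call. = FALSE)
  peak_ppm <- unlist(peak_ppm)
  if (is.null(names(peak_ppm)) || any(names(peak_ppm) == ""))
    stop("peak_ppm must be a named vector (metabolite -> ppm)", call. = FALSE)
  out_of_range <- peak_ppm < min(ppm_axis) | peak_ppm > max(ppm_axis)
  if (any(out_of_range))
    stop("peak positions outside ppm_axis: ",
         paste(names(peak_ppm)[out_of_range], collapse = ", "), call. = FALSE)
  structure(list(flip_angle = flip_angle, tr = tr,
                 n_timepoints = n_timepoints, ppm_axis = ppm_axis,
                 linewidth = linewidth, peak_ppm = peak_ppm),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("Acquisition: flip", x$flip_angle, "deg, TR", x$tr, "s,",
      x$n_timepoints, "timepoints\n")
  cat("ppm axis:", min(x$ppm_axis), "-", max(x$ppm_axis), "ppm (",
      length(x$ppm_axis), "points ), FWHM", x$linewidth, "ppm\n")
  cat("Peaks:", paste(sprintf("%s=%g", names(x$peak_ppm), x$peak_ppm),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Kinetic and bolus parameters of the exchange model
#'
#' Parameters of the linear exchange system for hyperpolarized pyruvate:
#' forward conversion to lactate at rate `kp` (LDH-catalyzed), optional
#' reverse rate `kl` (default 0, the usual irreversible approximation for
#' hyperpolarized fitting), optional parallel conversion to bicarbonate at
#' rate `kb` (PDH flux; default 0), longitudinal relaxation rates
#' `r1p`, `r1l`, `r1b` (1/T1, defaults corresponding to T1 = 30 s), and a
#' boxcar bolus input into the pyruvate pool (`bolus_amplitude` signal
#' units/s from `bolus_start` for `bolus_duration` seconds).
#'
#' @param kp forward pyruvate-to-lactate rate constant, 1/s (>= 0)
#' @param kl reverse lactate-to-pyruvate rate constant, 1/s (>= 0)
#' @param kb pyruvate-to-bicarbonate rate constant, 1/s (>= 0)
#' @param r1p,r1l,r1b longitudinal relaxation rates 1/T1, 1/s (>= 0)
#' @param bolus_start bolus onset, seconds from acquisition start
#' @param bolus_duration bolus duration in seconds (> 0)
#' @param bolus_amplitude input rate into the pyruvate pool, signal units/s
#' @return an object of class `kinetic_params`
#' @examples
#' kin <- kinetic_params(kp = 0.021)
#' @export
kinetic_params <- function(kp = 0.03, kl = 0, kb = 0,
                           r1p = 1 / 30, r1l = 1 / 30, r1b = 1 / 30,
                           bolus_start = 0, bolus_duration = 8,
                           bolus_amplitude = 1) {
  vals <- c(kp = kp, kl = kl, kb = kb, r1p = r1p, r1l = r1l, r1b = r1b,
            bolus_start = bolus_start, bolus_duration = bolus_duration,
            bolus_amplitude = bolus_amplitude)
  bad <- names(vals)[!is.finite(vals)]
  if (length(bad))
    stop("non-finite kinetic parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rates <- vals[c("kp", "kl", "kb", "r1p", "r1l", "r1b")]
  if (any(rates < 0))
    stop("rate(s) must be >= 0: ",
         paste(names(rates)[rates < 0], collapse = ", "), call. = FALSE)
  if (bolus_duration <= 0)
    stop("bolus_duration must be > 0", call. = FALSE)
  structure(as.list(vals), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Exchange: kp=%g kl=%g kb=%g 1/s; T1p=%.3g T1l=%.3g s\n",
              x$kp, x$kl, x$kb, 1 / x$r1p, 1 / x$r1l))
  cat(sprintf("Bolus: boxcar, start %g s, duration %g s, amplitude %g\n",
              x$bolus_start, x$bolus_duration, x$bolus_amplitude))
  invisible(x)
}

#' Specification of a synthetic two-group cohort
#'
#' Defines a two-group (e.g. normal diet vs high-fat diet) cohort: subjects
#' per group, the group means and between-animal standard deviation of the
#' true forward rate constant (draws truncated at 0), a per-group perfusion
#' scale multiplying the bolus amplitude, the spectral noise level, and an
#' optional linear behavior model linking the subject's noiseless
#' lactate/pyruvate ratio to a target-quadrant-time score
#' (`score = behavior_intercept - behavior_slope * ratio + noise`).
#'
#' @param n_per_group subjects per group (>= 1)
#' @param group_names labels for the two groups
#' @param group_kp_mean length-2 group means of the true kp, 1/s
#' @param group_kp_sd length-1 or length-2 between-subject SD of kp, 1/s
#' @param perfusion_mean,perfusion_sd per-group bolus-amplitude scale
#'   (length 1 or 2), arbitrary units
#' @param kb pyruvate-to-bicarbonate rate shared by all subjects, 1/s
#' @param noise_sd spectral-domain Gaussian noise SD, signal units
#' @param behavior_intercept,behavior_slope,behavior_sd linear behavior model;
#'   units of seconds in the target quadrant
#' @param seed integer seed; every random draw in the cohort flows from it
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = 5,
                        group_names = c("ND", "HFD"),
                        group_kp_mean = c(0.021, 0.056),
                        group_kp_sd = c(0.009, 0.015),
                        perfusion_mean = c(1.0, 0.7),
                        perfusion_sd = 0.08,
                        kb = 0.004,
                        noise_sd = 0,
                        behavior_intercept = 40,
                        behavior_slope = 30,
                        behavior_sd = 4,
                        seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (length(group_names) != 2L) stop("exactly two groups expected", call. = FALSE)
  if (length(group_kp_mean) != 2L || any(group_kp_mean < 0))
    stop("group_kp_mean must be two nonnegative rates", call. = FALSE)
  group_kp_sd <- rep_len(group_kp_sd, 2L)
  perfusion_mean <- rep_len(perfusion_mean, 2L)
  perfusion_sd <- rep_len(perfusion_sd, 2L)
  if (any(c(group_kp_sd, perfusion_sd, noise_sd, behavior_sd) < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(n_per_group = n_per_group, group_names = group_names,
                 group_kp_mean = group_kp_mean, group_kp_sd = group_kp_sd,
                 perfusion_mean = perfusion_mean, perfusion_sd = perfusion_sd,
                 kb = kb, noise_sd = noise_sd,
                 behavior_intercept = behavior_intercept,
                 behavior_slope = behavior_slope, behavior_sd = behavior_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}
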