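#' Dynamic lactate/pyruvate conversion ratio
#'
#' Pointwise ratio of the lactate to the pyruvate peak intensity, defined
#' only where pyruvate exceeds the floor (ratio maps and curves blow up at
#' vanishing pyruvate). The scalar summary is the mean ratio over the valid
#' window, which runs from the first to the last valid point; at least three
#' valid points are required.
#'
#' @param series a [dynamic_series()] containing `pyruvate` and `lactate`
#' @param floor absolute pyruvate intensity floor; by default 5 times the
#'   series' recorded noise level (0 for noiseless input)
#' @return list of class `ratio_curve`: `time_axis`, `ratio` (NA outside the
#'   valid window), `valid_mask`, `summary`
#' @export
ratio_curve <- function(series, floor = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  p <- series$intensities$pyruvate
  l <- series$intensities$lactate
  if (is.null(p) || is.null(l))
    stop("series must contain pyruvate and lactate", call. = FALSE)
  if (is.null(floor)) {
    nl <- series$provenance$noise_level
    floor <- if (is.null(nl)) 0 else 5 * nl
  }
  valid <- p > floor
  if (sum(valid) < 3)
    stop("fewer than 3 timepoints with pyruvate above the floor (",
         sum(valid), " valid of ", length(p), "); cannot form a ratio curve",
         call. = FALSE)
  ratio <- rep(NA_real_, length(p))
  ratio[valid] <- l[valid] / p[valid]
  structure(list(time_axis = series$time_axis, ratio = ratio,
                 valid_mask = valid, floor = floor,
                 summary = mean(ratio[valid])),
            class = "ratio_curve")
}

#' @export
print.ratio_curve <- function(x, ...) {
  cat(sprintf("Lactate/pyruvate ratio: %d valid points, summary %.4f\n",
              sum(x$valid_mask), x$summary))
  invisible(x)
}

#' Lactate/bicarbonate peak-intensity ratio
#'
#' Ratio of the maximum-over-time lactate intensity to the maximum-over-time
#' bicarbonate intensity: a contrast of cytosolic glycolysis (LDH flux)
#' against mitochondrial PDH flux. Fails with a "bicarbonate undetected"
#' diagnostic when the bicarbonate peak does not rise above the floor.
#'
#' @param series a [dynamic_series()] containing `lactate` and `bicarbonate`
#' @param floor absolute intensity floor for the bicarbonate peak; by default
#'   5 times the series' recorded noise level (0 for noiseless input)
#' @return scalar ratio
#' @export
lac_bic_ratio <- function(series, floor = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  l <- series$intensities$lactate
  b <- series$intensities$bicarbonate
  if (is.null(l) || is.null(b))
    stop("series must contain lactate and bicarbonate", call. = FALSE)
  if (is.null(floor)) {
    nl <- series$provenance$noise_level
    floor <- if (is.null(nl)) 0 else 5 * nl
  }
  peak_b <- max(b)
  if (peak_b <= floor)
    stop("bicarbonate undetected: peak intensity ", signif(peak_b, 4),
         " does not exceed floor ", signif(floor, 4), call. = FALSE)
  max(l) / peak_b
}

#' Model-free kP estimate from areas under the curves
#'
#' Under irreversible exchange the time integrals of the lactate and
#' pyruvate curves satisfy `AUC_L / AUC_P = kp / r1l_eff`, where `r1l_eff`
#' folds the per-excitation flip-angle loss into an effective relaxation
#' rate, `r1_eff = r1 - log(cos(flip)) / tr`. Inverting this identity gives
#' a one-line estimator that is independent of the least-squares fit and of
#' the bolus shape.
#'
#' @param series a [dynamic_series()] with `pyruvate` and `lactate`
#' @param acq an [acquisition_params()]
#' @param r1l lactate relaxation rate 1/s (default T1 = 30 s)
#' @param kl reverse rate 1/s (default 0)
#' @return scalar kp estimate, 1/s
#' @export
kp_from_auc <- function(series, acq, r1l = 1 / 30, kl = 0) {
  stopifnot(inherits(series, "dynamic_series"), inherits(acq, "acq_params"))
  theta <- acq$flip_angle * pi / 180
  r1l_eff <- r1l + kl - log(cos(theta)) / acq$tr
  auc_p <- pracma::trapz(series$time_axis, series$intensities$pyruvate)
  auc_l <- pracma::trapz(series$time_axis, series$intensities$lactate)
  if (auc_p <= 0) stop("pyruvate AUC is not positive", call. = FALSE)
  (auc_l / auc_p) * r1l_eff
}

#' Estimate the pyruvate-to-lactate rate constant kP
#'
#' Fits the lactate arm of the two-site exchange model to the quantified
#' peak-intensity time courses by nonlinear least squares. The measured
#' pyruvate series drives the lactate differential equation directly
#' (input-function-free fitting), so no arterial-input/bolus shape is
#' assumed:
#' \deqn{dL/dt = kp P(t) - (r1l + kl - log(cos\theta)/TR) L}
#' with the per-excitation flip-angle loss folded into an effective
#' relaxation rate. The equation is integrated exactly per sampling interval
#' with the measured pyruvate interpolated linearly. The single free
#' parameter kp is estimated with bounded Levenberg-Marquardt least squares
#' (init 0.03 1/s, bounds [0, 1] 1/s, relative tolerance 1e-8), restarted
#' from two further initial values on non-convergence.
#'
#' @param series a [dynamic_series()] with `pyruvate` and `lactate`
#' @param acq an [acquisition_params()]
#' @param r1l lactate longitudinal relaxation rate, 1/s (fixed; default
#'   T1 = 30 s)
#' @param kl reverse rate, 1/s (fixed; default 0)
#' @param init initial kp value, 1/s
#' @param bounds length-2 box constraint on kp, 1/s
#' @return list of class `kinetic_fit`: `kp_hat`, fixed parameters,
#'   `residual_norm`, `converged`, `at_bound`, `kp_se` (from the
#'   finite-difference Jacobian), `fitted` lactate series
#' @export
fit_kp <- function(series, acq, r1l = 1 / 30, kl = 0,
                   init = 0.03, bounds = c(0, 1)) {
  stopifnot(inherits(series, "dynamic_series"), inherits(acq, "acq_params"))
  p <- series$intensities$pyruvate
  l <- series$intensities$lactate
  if (is.null(p) || is.null(l))
    stop("series must contain pyruvate and lactate", call. = FALSE)
  if (length(p) < 10)
    stop("at least 10 timepoints required to fit kp", call. = FALSE)
  theta <- acq$flip_angle * pi / 180
  b_eff <- r1l + kl - log(cos(theta)) / acq$tr

  # the model is linear in kp: predicted lactate = kp * conv, with conv the
  # unit-rate solution of dL/dt = P(t) - b_eff L driven by the measured
  # pyruvate (piecewise-linear), integrated in closed form per interval
  conv <- .drive_lactate(series$time_axis, p, b_eff)

  resid_fn <- function(par) par[["kp"]] * conv - l
  fit <- NULL
  for (start in c(init, 0.005, 0.2)) {
    fit <- minpack.lm::nls.lm(
      par = c(kp = start), lower = bounds[1], upper = bounds[2],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                           maxiter = 200))
    if (fit$info %in% 1:4) break
  }
  kp_hat <- unname(stats::coef(fit)[["kp"]])
  res <- resid_fn(c(kp = kp_hat))
  rn <- sqrt(sum(res^2))
  dof <- max(length(l) - 1, 1)
  sigma2 <- sum(res^2) / dof
  jtj <- sum(conv^2)
  kp_se <- if (jtj > 0) sqrt(sigma2 / jtj) else NA_real_
  at_bound <- kp_hat <= bounds[1] + 1e-12 || kp_hat >= bounds[2] - 1e-12
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("kp fit did not converge (", fit$message, "); estimate reported",
            call. = FALSE)
  structure(list(kp_hat = kp_hat, r1l = r1l, kl = kl,
                 r1l_eff = b_eff, residual_norm = rn, kp_se = kp_se,
                 converged = converged, at_bound = at_bound,
                 n_points = length(l), fitted = kp_hat * conv,
                 optim_info = fit$info),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kp_hat = %.5f 1/s (SE %.2g), residual norm %.3g, %s\n",
              x$kp_hat, x$kp_se, x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  if (x$at_bound) cat("warning: estimate at a bound\n")
  invisible(x)
}

# Unit-rate lactate response: solves y' = P(t) - b*y, y(0)=0, with P
# piecewise linear through the samples; exact per-interval update.
.drive_lactate <- function(t, p, b) {
  n <- length(t)
  y <- numeric(n)
  for (k in seq_len(n - 1)) {
    dt <- t[k + 1] - t[k]
    p0 <- p[k]
    slope <- (p[k + 1] - p[k]) / dt
    e <- exp(-b * dt)
    if (b > 0) {
      y[k + 1] <- y[k] * e + p0 * (1 - e) / b +
        slope * (dt / b - (1 - e) / b^2)
    } else {
      y[k + 1] <- y[k] + p0 * dt + slope * dt^2 / 2
    }
  }
  y
}
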