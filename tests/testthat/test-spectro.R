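test_that("noiseless quantification round-trips the generator's series", {
  acq <- default_acq()
  ser <- simulate_exchange(kinetic_params(kp = 0.03), acq)
  sp <- synthesize_spectra(ser, acq, noise_sd = 0)
  q <- quantify_peaks(sp, acq)
  for (m in names(ser$intensities)) {
    scale <- max(ser$intensities[[m]])
    expect_lt(max(abs(q$intensities[[m]] - ser$intensities[[m]])) / scale,
              0.005)
  }
})

test_that("an all-zero matrix quantifies to zero with every point flagged", {
  acq <- default_acq(n_timepoints = 10)
  sp <- spectral_matrix(matrix(0, 10, length(acq$ppm_axis)),
                        acq$ppm_axis, 0:9)
  q <- quantify_peaks(sp, acq)
  expect_true(all(unlist(q$intensities) == 0))
  expect_true(all(unlist(q$flags)))
})

test_that("a lone lactate resonance is assigned to lactate only", {
  acq <- default_acq(n_timepoints = 5)
  line <- 50 * (0.5^2) / ((acq$ppm_axis - 185)^2 + 0.5^2)
  sp <- spectral_matrix(matrix(rep(line, 5), 5, byrow = TRUE),
                        acq$ppm_axis, 0:4)
  q <- quantify_peaks(sp, acq)
  expect_equal(q$intensities$lactate, rep(50, 5))
  expect_lt(max(q$intensities$pyruvate), 0.5)
  expect_equal(unname(q$provenance$located_ppm["lactate"]), 185)
})

test_that("quantification windows must be non-empty and disjoint", {
  acq <- default_acq()
  sp <- synthesize_spectra(simulate_exchange(kinetic_params(), acq), acq)
  expect_error(quantify_peaks(sp, acq, window_ppm = 7), "overlap")
  sparse <- acquisition_params(ppm_axis = c(150, 200),
                               peak_ppm = c(pyruvate = 173))
  sp2 <- spectral_matrix(matrix(0, 3, 2), c(150, 200), 0:2)
  expect_error(quantify_peaks(sp2, sparse, window_ppm = 2), "empty")
})

test_that("quantification is stable under ppm-axis refinement", {
  kin <- kinetic_params(kp = 0.03)
  coarse <- default_acq(ppm_axis = seq(150, 200, by = 0.2))
  fine <- default_acq(ppm_axis = seq(150, 200, by = 0.1))
  ser <- simulate_exchange(kin, coarse)
  q1 <- quantify_peaks(synthesize_spectra(ser, coarse), coarse)
  q2 <- quantify_peaks(synthesize_spectra(ser, fine), fine)
  for (m in c("pyruvate", "lactate")) {
    scale <- max(q1$intensities[[m]])
    expect_lt(max(abs(q1$intensities[[m]] - q2$intensities[[m]])) / scale,
              0.01)
  }
})

test_that("total 13C signal is zero on empty data and linear in intensity", {
  acq <- default_acq()
  n <- length(acq$ppm_axis)
  zero <- spectral_matrix(matrix(0, 20, n), acq$ppm_axis, 0:19)
  expect_equal(total_carbon_signal(zero, 0, 10), 0)

  ser <- simulate_exchange(kinetic_params(kp = 0.03), acq)
  sp <- synthesize_spectra(ser, acq)
  s1 <- total_carbon_signal(sp, 0, 10)
  sp2 <- spectral_matrix(2 * sp$data, sp$ppm_axis, sp$time_axis)
  expect_equal(total_carbon_signal(sp2, 0, 10), 2 * s1)
})

test_that("total signal scales with the injected bolus (perfusion contrast)", {
  acq <- default_acq()
  s <- vapply(c(1.0, 0.7), function(amp) {
    ser <- simulate_exchange(kinetic_params(kp = 0.03,
                                            bolus_amplitude = amp), acq)
    total_carbon_signal(synthesize_spectra(ser, acq), 0, 10)
  }, numeric(1))
  expect_equal(s[2] / s[1], 0.7, tolerance = 0.01)
})

test_that("total signal rejects windows truncated by the series end", {
  acq <- default_acq(n_timepoints = 20)
  sp <- synthesize_spectra(simulate_exchange(kinetic_params(), acq), acq)
  expect_error(total_carbon_signal(sp, 15, 10), "beyond")
})

test_that("total signal is invariant under ppm-axis reversal", {
  acq <- default_acq()
  sp <- synthesize_spectra(simulate_exchange(kinetic_params(kp = 0.04), acq),
                           acq)
  rev_sp <- spectral_matrix(sp$data[, ncol(sp$data):1],
                            rev(sp$ppm_axis), sp$time_axis)
  expect_equal(total_carbon_signal(rev_sp, 0, 10),
               total_carbon_signal(sp, 0, 10))
})
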