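test_that("no forward exchange gives identically zero lactate", {
  ser <- simulate_exchange(kinetic_params(kp = 0), default_acq())
  expect_equal(ser$intensities$lactate, rep(0, 90))
  expect_true(all(ser$intensities$pyruvate >= 0))
})

test_that("integrator matches the closed-form biexponential after an impulse", {
  kp <- 0.021
  acq <- default_acq(flip_angle = 1e-7)      # vanishing readout perturbation
  kin <- impulse_kin(kp, m0 = 1)
  ser <- simulate_exchange(kin, acq)
  ml <- ser$provenance$longitudinal[, "lactate"]
  t <- ser$time_axis
  expected <- biexp_lactate(t, 1, kp, kin$r1p, kin$r1l)
  sel <- t > 0
  expect_lt(max(abs(ml[sel] - expected[sel]) / expected[sel]), 1e-3)
})

test_that("lactate/pyruvate ratio is pointwise larger at higher kp", {
  acq <- default_acq()
  a <- simulate_exchange(kinetic_params(kp = 0.021), acq)
  b <- simulate_exchange(kinetic_params(kp = 0.056), acq)
  post <- a$time_axis > 8          # past bolus end
  ra <- a$intensities$lactate[post] / a$intensities$pyruvate[post]
  rb <- b$intensities$lactate[post] / b$intensities$pyruvate[post]
  expect_true(all(rb > ra))
})

test_that("polarization budget is nonincreasing once the bolus ends", {
  ser <- simulate_exchange(kinetic_params(kp = 0.03, kb = 0.005),
                           default_acq())
  total <- rowSums(ser$provenance$longitudinal)
  post <- which(ser$time_axis >= 8)
  expect_true(all(diff(total[post]) <= 1e-12))
})

test_that("larger flip angles consume the longitudinal budget faster", {
  kin <- kinetic_params(kp = 0.03)
  totals <- vapply(c(5, 10, 20, 40), function(fa) {
    ser <- simulate_exchange(kin, default_acq(flip_angle = fa))
    sum(ser$provenance$longitudinal[, "pyruvate"])
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("nonfinite kinetic input fails loudly with the parameter named", {
  expect_error(kinetic_params(r1p = Inf), "r1p")
})

test_that("spectral synthesis places peaks and is seed-deterministic", {
  acq <- default_acq()
  n <- acq$n_timepoints
  ser <- dynamic_series((0:(n - 1)) * acq$tr,
                        list(pyruvate = c(100, rep(0, n - 1)),
                             lactate = rep(0, n)))
  sp <- synthesize_spectra(ser, acq, noise_sd = 0)
  expect_equal(max(sp$data), 100)
  expect_equal(sp$ppm_axis[which.max(sp$data[1, ])], 173)
  expect_equal(max(abs(sp$data[-1, ])), 0)

  zero <- dynamic_series((0:(n - 1)) * acq$tr,
                         list(pyruvate = rep(0, n), lactate = rep(0, n)))
  expect_true(all(synthesize_spectra(zero, acq)$data == 0))

  s1 <- synthesize_spectra(ser, acq, noise_sd = 0.1, seed = 42)
  s2 <- synthesize_spectra(ser, acq, noise_sd = 0.1, seed = 42)
  expect_identical(s1$data, s2$data)
  s3 <- synthesize_spectra(ser, acq, noise_sd = 0.1, seed = 43)
  expect_false(identical(s1$data, s3$data))
})

test_that("peak overlap closer than twice the linewidth is recorded", {
  acq <- acquisition_params(peak_ppm = c(pyruvate = 173, lactate = 174),
                            linewidth = 1)
  ser <- simulate_exchange(kinetic_params(kp = 0.03), acq)
  sp <- synthesize_spectra(ser, acq)
  expect_match(sp$provenance$warnings, "overlap")
})

test_that("cohort generator honors sizes, degenerate SDs and seeds", {
  acq <- default_acq(n_timepoints = 30)
  co1 <- simulate_cohort(cohort_spec(n_per_group = 1, seed = 5), acq)
  expect_equal(nrow(co1$truth), 2L)

  degen <- cohort_spec(n_per_group = 3, group_kp_sd = 0, perfusion_sd = 0,
                       seed = 5)
  cod <- simulate_cohort(degen, acq)
  expect_equal(cod$truth$kp_true,
               rep(c(0.021, 0.056), each = 3), tolerance = 1e-12)

  co2 <- simulate_cohort(cohort_spec(n_per_group = 2, seed = 9), acq)
  co3 <- simulate_cohort(cohort_spec(n_per_group = 2, seed = 9), acq)
  expect_identical(co2$truth, co3$truth)
  expect_true(all(co2$truth$kp_true >= 0))
})

test_that("CSI phantom carries geometry and regional kinetics", {
  acq <- default_acq()
  masks <- csi_phantom_masks(18, 24)
  rk <- list(cortex = kinetic_params(kp = 0.021),
             hippocampus = kinetic_params(kp = 0.042),
             striatum = kinetic_params(kp = 0.042),
             vascular = kinetic_params(kp = 0, bolus_amplitude = 2))
  grid <- simulate_csi(rk, acq, masks, fov = c(18, 24))
  expect_equal(grid$geometry$resolution, c(1, 1))
  expect_equal(grid$geometry$matrix_size, c(18L, 24L))

  # vascular voxels carry no lactate component: the generator's ground truth
  # is exactly zero and anything in the lactate window is pure Lorentzian
  # tail of the (strong) pyruvate resonance, under half a percent of it
  expect_equal(grid$provenance$region_truth["vascular", "lactate"], 0)
  lac <- metabolite_map(grid, "lactate", acq)
  pyr <- metabolite_map(grid, "pyruvate", acq)
  vas <- masks$vascular
  expect_true(all(lac$values[vas] < 0.005 * pyr$values[vas]))

  # doubled hippocampal kp means a higher lactate/pyruvate ratio there
  lac <- metabolite_map(grid, "lactate", acq)
  pyr <- metabolite_map(grid, "pyruvate", acq)
  rat <- ratio_map(lac, pyr)
  expect_gt(roi_stats(rat, "hippocampus", masks)$mean,
            roi_stats(rat, "cortex", masks)$mean)
})

test_that("mask shape mismatches are rejected", {
  masks <- csi_phantom_masks(18, 24)
  masks$cortex <- masks$cortex[1:9, ]
  expect_error(simulate_csi(list(cortex = kinetic_params()), default_acq(),
                            masks),
               "shape")
})
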