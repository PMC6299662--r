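make_phantom <- function(noise_sd = 0, seed = NULL, nrow = 18, ncol = 24,
                         kp_cortex = 0.021, hippo_factor = 2,
                         vascular = TRUE) {
  acq <- default_acq()
  masks <- csi_phantom_masks(nrow, ncol)
  rk <- list(cortex = kinetic_params(kp = kp_cortex),
             hippocampus = kinetic_params(kp = hippo_factor * kp_cortex),
             striatum = kinetic_params(kp = hippo_factor * kp_cortex),
             vascular = kinetic_params(kp = 0, bolus_amplitude = 2))
  if (!vascular) rk$vascular <- NULL
  list(grid = simulate_csi(rk, acq, masks, noise_sd = noise_sd, seed = seed),
       acq = acq, masks = masks, rk = rk)
}

test_that("all-zero grids yield all-invalid maps and unknown labels fail", {
  acq <- default_acq()
  grid <- spectra_grid(array(0, c(6, 8, length(acq$ppm_axis))),
                       acq$ppm_axis, fov = c(6, 8))
  map <- metabolite_map(grid, "pyruvate", acq)
  expect_false(any(map$valid))
  expect_error(metabolite_map(grid, "alanine", acq), "unknown metabolite")
})

test_that("phantom maps round-trip the generator's voxel intensities", {
  ph <- make_phantom()
  truth <- ph$grid$provenance$region_truth
  for (met in c("pyruvate", "lactate")) {
    map <- metabolite_map(ph$grid, met, ph$acq)
    for (rg in c("cortex", "hippocampus", "striatum")) {
      vox <- ph$masks[[rg]] & map$valid
      expect_gt(sum(vox), 0)
      expect_equal(mean(map$values[vox]), truth[rg, met], tolerance = 0.01)
    }
  }
})

test_that("map geometry records the stated in-plane resolution", {
  ph <- make_phantom()
  map <- metabolite_map(ph$grid, "pyruvate", ph$acq)
  expect_equal(map$geometry$resolution, c(1, 1))
  expect_equal(csi_resolution(c(18, 24), c(18, 24)), c(1, 1))
})

test_that("ratio maps divide elementwise and propagate validity", {
  ph <- make_phantom()
  pyr <- metabolite_map(ph$grid, "pyruvate", ph$acq)
  rat_self <- ratio_map(pyr, pyr)
  expect_true(all(rat_self$values[rat_self$valid] == 1))

  lac <- metabolite_map(ph$grid, "lactate", ph$acq)
  # invalidate one pyruvate voxel -> the ratio is invalid there
  vox <- which(pyr$valid, arr.ind = TRUE)[1, ]
  pyr$valid[vox[1], vox[2]] <- FALSE
  rat <- ratio_map(lac, pyr)
  expect_false(rat$valid[vox[1], vox[2]])
  expect_true(is.na(rat$values[vox[1], vox[2]]))

  other <- metabolite_map(make_phantom(nrow = 9, ncol = 12)$grid,
                          "pyruvate", ph$acq)
  expect_error(ratio_map(lac, other), "geometry")
})

test_that("regional ratios are highest where kinetics are fastest", {
  ph <- make_phantom()
  lac <- metabolite_map(ph$grid, "lactate", ph$acq)
  pyr <- metabolite_map(ph$grid, "pyruvate", ph$acq)
  rat <- ratio_map(lac, pyr)
  expect_gt(roi_stats(rat, "hippocampus", ph$masks)$mean,
            roi_stats(rat, "cortex", ph$masks)$mean)
  expect_gt(roi_stats(rat, "striatum", ph$masks)$mean,
            roi_stats(rat, "cortex", ph$masks)$mean)
})

test_that("ROI statistics pool consistently and guard empty masks", {
  ph <- make_phantom()
  map <- metabolite_map(ph$grid, "lactate", ph$acq)
  uni <- map
  uni$values[] <- 3.5
  st <- roi_stats(uni, "whole_brain", ph$masks)
  expect_equal(st$mean, 3.5)
  expect_equal(st$sd, 0)

  # pooled mean over a partition equals the count-weighted combination
  a <- roi_stats(map, ph$masks$hippocampus)
  b <- roi_stats(map, ph$masks$whole_brain & !ph$masks$hippocampus)
  whole <- roi_stats(map, "whole_brain", ph$masks)
  expect_equal(whole$mean,
               (a$mean * a$n_valid + b$mean * b$n_valid) /
                 (a$n_valid + b$n_valid))

  empty <- matrix(FALSE, 18, 24)
  expect_error(roi_stats(map, empty), "no valid voxels")
})

test_that("2x2 downsampling to the coarser matrix barely moves ROI ratios", {
  # smooth phantom: parenchyma only, so block averaging mixes voxels whose
  # lactate and pyruvate scale together and the ratio stays put
  ph <- make_phantom(vascular = FALSE)
  down <- downsample_grid(ph$grid, 2)
  expect_equal(down$geometry$matrix_size, c(9L, 12L))
  expect_equal(down$geometry$resolution, c(2, 2))
  for (g in list(ph$grid, down)) {
    lac <- metabolite_map(g, "lactate", ph$acq)
    pyr <- metabolite_map(g, "pyruvate", ph$acq)
    rat <- ratio_map(lac, pyr)
    st <- roi_stats(rat, "whole_brain", g$masks)
    if (identical(g, ph$grid)) fine <- st$mean else coarse <- st$mean
  }
  expect_lt(abs(coarse - fine) / fine, 0.05)
})
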