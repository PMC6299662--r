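# hyperpyr

Analysis of hyperpolarized [1-¹³C]pyruvate magnetic resonance spectroscopy
(MRS) of brain metabolism, aimed at preclinical imaging groups measuring
pyruvate-to-lactate conversion as a glycolysis biomarker (e.g. in
diet-induced metabolic disease models).

Dissolution dynamic nuclear polarization makes the conversion of injected
[1-¹³C]pyruvate to [1-¹³C]lactate observable in vivo in real time. The
package covers the whole desk-side analysis chain:

* **Forward model** — two-site exchange (modified Bloch) kinetics of the
  longitudinal magnetizations,

  dMₚ/dt = −(ρₚ + kₚ)Mₚ + k_L M_L + u(t),  dM_L/dt = kₚMₚ − (ρ_L + k_L)M_L,

  with T1 relaxation (ρ = 1/T1), a boxcar bolus u(t), optional parallel
  bicarbonate production, and per-excitation flip-angle depletion
  (each RF pulse reads out sin θ·Mz and leaves cos θ·Mz). Propagation uses
  exact matrix exponentials — no integration-step error.
* **Spectral layer** — Lorentzian synthesis of time × ppm matrices
  (pyruvate 173 ppm, lactate 185 ppm, bicarbonate 161 ppm) and windowed
  peak quantification with SNR flagging.
* **Kinetics** — the apparent rate constant kₚ (s⁻¹) by input-function-free
  least squares (the measured pyruvate drives the lactate ODE), the dynamic
  lactate/pyruvate ratio, the lactate/bicarbonate ratio, a model-free AUC
  estimator as a cross-check, and the total ¹³C signal (perfusion
  surrogate).
* **CSI maps** — single-timepoint chemical shift imaging grids, metabolite
  and ratio maps with SNR gating, ROI statistics, NIfTI export.
* **Cohorts** — seeded two-group synthetic cohorts with known ground truth,
  Welch t tests (means ± SEM), Pearson correlations, and object-location
  behavior indices (preference %, discrimination index).
* **Pipeline** — `run_pipeline()` runs simulate → quantify → kinetics →
  csimap → stats from one YAML/JSON/list config, writes CSV/JSON products
  and a hashed manifest, and is byte-reproducible for a fixed seed.

## Worked example

Simulate one high-conversion subject at kₚ = 0.056 s⁻¹ (10° flip, TR 1 s,
90 timepoints), render noisy spectra, quantify, and re-estimate the rate:

```r
library(hyperpyr)

acq  <- acquisition_params()          # 10 deg, TR 1 s, 90 pts, 150-200 ppm
ser  <- simulate_exchange(kinetic_params(kp = 0.056), acq)
spec <- synthesize_spectra(ser, acq, noise_sd = 0.02, seed = 42)
q    <- quantify_peaks(spec, acq)

fit_kp(q, acq)
#> kp_hat = 0.05460 1/s (SE 0.00064), residual norm 0.22, converged

ratio_curve(q)
#> Lactate/pyruvate ratio: 29 valid points, summary 1.1040

total_carbon_signal(spec, 0, 10)
#> [1] 11.36355

behavior_indices(30, 10)
#>   preference_pct discrimination_index
#> 1             75                  0.5
```

The fitted `kp_hat` of 0.0546 s⁻¹ recovers the generating 0.056 s⁻¹ to
about 2.5 % at this noise level (exactly, at zero noise); the ratio summary
is the mean lactate/pyruvate over the timepoints where pyruvate clears the
SNR floor; the total signal is the area under the whole spectrum summed
over the first 10 s after injection; and 30 s vs 10 s of exploration gives
75 % preference and a discrimination index of 0.5.

An end-to-end cohort run:

```r
run_pipeline(list(seed = 7, out_dir = "demo_run",
                  cohort = list(n_per_group = 5, noise_sd = 0.03)))
# -> demo_run/{truth,cohort,roi_stats}.csv, stats_report.json, manifest.json
```

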