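---
title: "Modeling and analyzing hyperpolarized [1-13C]pyruvate MRS of brain metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analyzing hyperpolarized [1-13C]pyruvate MRS of brain metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperpyr)
```

## The experiment and its model

Dissolution dynamic nuclear polarization boosts the nuclear polarization of
[1-13C]pyruvate by four orders of magnitude, enough to watch its enzymatic
conversion to [1-13C]lactate (by lactate dehydrogenase) and 13C-bicarbonate
(by pyruvate dehydrogenase, via CO2) in a living brain in real time. The
polarization is non-renewable: it decays with T1 and every radiofrequency
excitation consumes a fraction of it. A typical dynamic protocol excites a
brain slice every second with a small (10 degree) flip angle for about 90 s
and records one spectrum per excitation; pyruvate appears at 173 ppm,
lactate at 185 ppm and bicarbonate near 161 ppm.

`hyperpyr` models the longitudinal magnetizations with the standard two-site
exchange (modified Bloch / Bloch-McConnell) system, optionally extended with
a parallel bicarbonate pool:

$$
\frac{dM_P}{dt} = -(\rho_P + k_P + k_B)\,M_P + k_L M_L + u(t), \qquad
\frac{dM_L}{dt} = k_P M_P - (\rho_L + k_L)\,M_L, \qquad
\frac{dM_B}{dt} = k_B M_P - \rho_B M_B,
$$

where $k_P$ (s$^{-1}$) is the apparent pyruvate-to-lactate rate constant —
the quantity of biological interest — $\rho_X = 1/T_{1,X}$ are relaxation
rates, $k_L$ a reverse rate, and $u(t)$ the bolus input. Each excitation at
flip angle $\theta$ reads out a signal proportional to $\sin\theta\,M_z$ and
leaves $\cos\theta\,M_z$ behind. `simulate_exchange()` applies this
depletion as a discrete $\cos\theta$ multiplication at every TR rather than
folding it into an effective rate, which keeps the forward model exact for
arbitrary flip schedules. Between excitations the affine linear system is
propagated with exact matrix exponentials, with breakpoints at the bolus
edges, so there is no integration-step error at all: the spec of the
sampling grid is the only discretization.

### Assumptions and defaults

* **Irreversibility** ($k_L = 0$ by default): at the SNR of a 90-point
  series the reverse rate is not identifiable, and hyperpolarized fitting
  conventionally reports only the forward constant. $k_L$ remains a
  parameter for sensitivity studies.
* **Relaxation**: $T_{1P} = T_{1L} = T_{1B} = 30$ s by default, a typical
  in-vivo value for carboxyl 13C at high field; all configurable. Estimates
  of $k_P$ trade off directly against the assumed $T_{1L}$, so cross-study
  comparisons should fix these the same way.
* **Bolus**: a boxcar input (start 0 s, duration 8 s, amplitude 1 unit/s).
  Nothing downstream assumes this shape — the fitter never sees it — so it
  is a convenience for the generator only. Bolus timing relative to
  acquisition start is a free configuration parameter.
* **Lineshape**: Lorentzian, default FWHM 0.4 ppm, i.e. roughly 40 Hz at a
  9.4 T carbon frequency — a realistic in-vivo linewidth. Broader lines
  leak measurable tail intensity from the large pyruvate resonance into the
  12-ppm-distant lactate and bicarbonate windows; with 0.4 ppm the leak is
  below half a percent of the respective peak.
* **Noise**: additive iid Gaussian in the spectral domain, the simplest
  model consistent with magnitude peak readout at moderate-to-high SNR. Rician
  floor effects at very low SNR are not modeled.

## Quantification

`quantify_peaks()` takes, per timepoint and metabolite, the maximum
magnitude within ±2 ppm of the nominal shift — the "peak value" of each
metabolite, robust at desk scale, with no lineshape fitting (a trapezoidal
`integral = TRUE` variant exists). The noise level is the median absolute
deviation of the signal-free ppm bins; points below 5× that level are kept
but flagged low-confidence. A consequence of the windowed maximum worth
knowing: in pure noise the expected maximum of ~20 magnitude bins is about
2σ, so very weak peaks are read slightly high. At a bolus-peak SNR of 30
this inflates a control-level $k_P$ fit by roughly 15 % on average, while
cohort-level aggregates (both groups pooled) stay within a few percent;
at noiseless or high SNR the effect vanishes.

`total_carbon_signal()` integrates the magnitude spectrum across the full
ppm axis (trapezoid) and sums the first 10 s from the injection — a
perfusion surrogate: half-open window, and a window truncated by the end of
the acquisition is an error rather than a silent partial sum.

## Rate-constant fitting

`fit_kp()` is input-function-free: the *measured* pyruvate series drives
the lactate equation, so no bolus model is ever fitted,

$$
\frac{dL}{dt} = k_P\,P_\mathrm{meas}(t) -
  \Big(\rho_L + k_L - \tfrac{\ln\cos\theta}{TR}\Big) L .
$$

Here the discrete per-TR $\cos\theta$ losses are folded into an effective
relaxation rate — exact at the sample times for the pyruvate factor (since
$\cos^k\theta = e^{k\ln\cos\theta}$) and accurate well within the stated
tolerances for the cross term at 10°/1 s: the noiseless round trip through
simulation, spectral synthesis, quantification and fitting recovers
0.021 s$^{-1}$ and 0.056 s$^{-1}$ to better than 0.5 %. The measured
pyruvate is interpolated linearly within each TR and the lactate ODE is
integrated in closed form per interval, making the predicted lactate series
linear in $k_P$; the single parameter is nevertheless estimated with
bounded Levenberg–Marquardt (init 0.03 s$^{-1}$, bounds [0, 1] s$^{-1}$,
relative tolerance $10^{-8}$, two restarts on non-convergence) so the
machinery generalizes if more parameters are freed. Estimates at a bound
and non-converged fits are flagged, and a finite-sample standard error is
reported from the Jacobian.

Two independent checks accompany the fitter: the closed-form biexponential
solution of the irreversible impulse-response, and the model-free AUC
identity $\int L\,dt / \int P\,dt = k_P / \rho_{L,\mathrm{eff}}$
(`kp_from_auc()`), which agrees with the least-squares estimate within 10 %
on clean data (its residual difference is the 90 s truncation of the
integrals).

## Ratio metrics

`ratio_curve()` forms the pointwise lactate/pyruvate ratio wherever
pyruvate exceeds a floor (default 5× the recorded noise level) and
summarizes it as the mean over the valid window — the window runs from the
first to the last valid point, a choice the data themselves cannot dictate.
`lac_bic_ratio()` divides the over-time maxima of lactate and bicarbonate
and refuses to report anything when bicarbonate never clears the floor
("bicarbonate undetected"), since that ratio diverges exactly when its
denominator is noise.

## CSI maps

`simulate_csi()` builds a single-timepoint chemical-shift-imaging phantom:
disjoint kinetic regions (cortex, hippocampus, striatum, a vascular rim)
evolve undisturbed from injection to the acquisition delay (default 18 s)
and are read out once. Geometry metadata records FOV, matrix, slice
thickness and the derived in-plane resolution (FOV/matrix; 18 × 24 mm at
matrix 18 × 24 gives 1 × 1 mm). `metabolite_map()` applies the same
windowed-maximum readout per voxel, gating validity at 5× the grid's robust
noise (ratio maps explode at low pyruvate, so the gate propagates through
`ratio_map()` via mask intersection). `roi_stats()` reports mean, SD and
the number of valid voxels per named mask; `downsample_grid()` emulates the
coarser 9 × 12 acquisition matrix by 2 × 2 voxel averaging. Overlay on
anatomical images is deliberately out of scope — maps export to NIfTI with
voxel dimensions from the geometry, and any registration happens elsewhere.

## Cohorts and statistics

`simulate_cohort()` draws subject-level $k_P$ from each group's normal
distribution truncated at zero (defaults 0.021 ± 0.009 vs
0.056 ± 0.015 s$^{-1}$, five per group), a per-group perfusion scale on the
bolus amplitude (1.0 vs 0.7, SD 0.08, emulating reduced delivery), and
behavior scores linked linearly to each subject's noiseless
lactate/pyruvate ratio (`target_time = 40 − 30·ratio + N(0, 4)` seconds),
plus object-location exploration times from a latent discrimination index
tied to the same ratio. Every draw flows from one explicit seed through an
isolated RNG; the global random state is never touched.

`two_group_test()` is Welch's t by default (pooled-variance behind a flag;
the choice matters little at n = 5 but unequal variances are the safer
default), reporting group means ± SEM as this literature does.
`pearson_correlation()` reports r, two-sided p and the n actually used.
`behavior_indices()` implements preference
$= 100\,T_{novel}/(T_{novel}+T_{familiar})$ and the discrimination index
$DI = (T_{novel}-T_{familiar})/(T_{novel}+T_{familiar})$. No
multiple-testing correction is applied across the metric family, and the
output metadata says so. Longitudinal/mixed modeling of the dynamic curves
is exported as tidy tables for external tools rather than reimplemented.

## What the synthetic data do and do not establish

The generator reproduces the *statistical structure* the analysis assumes:
bolus-driven arrival, irreversible-dominant exchange, T1 plus flip-angle
decay, Lorentzian peaks with Gaussian noise, between-animal variance at the
two group means, and regional CSI contrast. Passing round-trip tests
therefore establishes internal consistency — the estimator recovers the
parameters of the model that generated the data — and the noisy-recovery
suite bounds estimator error under the assumed noise. They do not establish
robustness to what real data add: B0 drift and lineshape distortion,
baseline roll, partial-volume and coil-sensitivity effects, a dispersive
(non-boxcar) arterial input, or metabolite T1s differing from the assumed
30 s. Conclusions about real cohorts inherit those assumptions.

## Numerical choices and degenerate inputs

Propagation is exact (matrix exponentials of a 4 × 4 affine generator,
cached per step length), so stiffness cannot arise for finite nonnegative
rates; non-finite parameters are rejected by name at construction. Windowed
maxima are taken on magnitude spectra, so negative heights cannot occur.
Degenerate guards are hard errors, not warnings: fewer than three valid
ratio points, pyruvate never above floor, both exploration times zero,
zero variance in both groups, empty ROI intersections, truncated signal
windows, mask/grid shape mismatches, and unknown configuration keys (schema
checked before any stage runs). Tie-break in the peak search is R's
`which.max` (first bin), which only matters on exactly flat windows.

Problem sizes used throughout the tests are desk scale by design — 90-point
series, 18 × 24 grids, 50-seed recovery sweeps, cohorts of 2 × 5 — the
scale of the experiments themselves.

## Known limitations

* Single-compartment kinetics: no vascular/extravascular exchange model.
* No k-space/phase-encoding simulation; CSI is generated at the spectral
  grid level, alanine is unmodeled.
* The windowed-maximum quantifier is biased upward for peaks at or below
  the noise level (see above); lineshape fitting would remove this at the
  cost of the robustness the peak-value readout buys at desk scale.
* Ratio summaries depend on the valid-window convention; comparisons
  across settings must hold the floor fixed.
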