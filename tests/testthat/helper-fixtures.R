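# Shared fixtures: a default acquisition and closed-form oracles.

default_acq <- function(...) acquisition_params(...)

# Analytic lactate magnetization for irreversible exchange after an impulse
# M0 of pyruvate at t = 0 (no RF depletion):
#   Ml(t) = M0 kp (exp(-a t) - exp(-b t)) / (b - a),  a = r1p + kp, b = r1l
biexp_lactate <- function(t, m0, kp, r1p, r1l) {
  a <- r1p + kp
  b <- r1l
  m0 * kp * (exp(-a * t) - exp(-b * t)) / (b - a)
}

# Welch t statistic written out from the textbook formula.
welch_t_oracle <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
}

# A near-impulse bolus: M0 delivered over a negligible 0.1 ms boxcar.
impulse_kin <- function(kp, m0 = 1, r1p = 1 / 30, r1l = 1 / 30, ...) {
  dur <- 1e-4
  kinetic_params(kp = kp, r1p = r1p, r1l = r1l, bolus_start = 0,
                 bolus_duration = dur, bolus_amplitude = m0 / dur, ...)
}
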