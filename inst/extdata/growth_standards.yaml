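# Growth-standard coefficient registry.
#
# Each standard provides, per biometric plane, a gestational-age-from-measurement
# curve as a polynomial: ga = c0 + c1*x + c2*x^2 + c3*x^3 with x the measurement
# in `measurement_unit` and ga in `ga_unit`. Curves must be strictly increasing
# in the measurement over the bracket searched (all non-intercept coefficients
# >= 0). `valid_ga_days` is the tabulated range; outside it the same polynomial
# is extrapolated and results are flagged out-of-range, never clamped.
#
# The default `hadlock` standard uses the published Hadlock dating polynomials
# (measurement in cm, GA in weeks), the Hadlock three-parameter log10 EFW
# formula (HC/AC/FL in cm, EFW in grams) and the Hadlock in-utero EFW-for-GA
# reference: ln(EFW) as a quadratic in GA (weeks) with a constant log-scale SD
# (approximately a 12.7% coefficient of variation).
standards:
  hadlock:
    description: Hadlock dating curves, three-parameter EFW and in-utero EFW-for-GA reference
    planes:
      HC:
        measurement_unit: cm
        ga_unit: weeks
        coefficients: [8.96, 0.540, 0.0, 0.0003]
        valid_ga_days: [84, 294]
      AC:
        measurement_unit: cm
        ga_unit: weeks
        coefficients: [8.14, 0.753, 0.0036]
        valid_ga_days: [84, 294]
      FL:
        measurement_unit: cm
        ga_unit: weeks
        coefficients: [10.35, 2.460, 0.170]
        valid_ga_days: [84, 294]
    efw:
      type: log10_cm
      coefficients:
        intercept: 1.326
        hc: 0.0107
        ac: 0.0438
        fl: 0.158
        ac_fl: -0.00326
    efw_reference:
      type: log_quadratic_weeks
      mean_coefficients: [0.578, 0.332, -0.00354]
      log_sd: 0.127
      valid_ga_days: [70, 294]
    centile_cutoffs:
      sga: 0.10
      lga: 0.90
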