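# scanbias

Detection and quantification of **expected-value (observer) bias** in routine
fetal growth ultrasound scans, for researchers studying measurement quality in
obstetric imaging.

During a growth scan the operator measures head circumference (HC), abdominal
circumference (AC) and femur length (FL). While the calipers are being
adjusted, the scanner's *measurement box* displays the current value and the
gestational age (GA) it implies. An operator who knows the pregnancy's dating
GA — the *expected value* `E` — and who looks at that box before saving can,
consciously or not, steer the measurement so that the *observed value* `O`
(the GA implied by the measurement through a growth-standard curve) moves
toward `E`. `scanbias` takes operator eye-tracking streams and
measurement-event logs, finds the moments this opportunity arises, and
quantifies what it does to the measurements and to the estimated fetal
weight (EFW).

## What it computes

* **Fixations on the measurement box** — dwell episodes of the gaze on the box
  rectangle, merging interruptions ≤ 400 ms and keeping episodes ≥ 100 ms.
* **Bias events** — a measurement is *biased* when at least one such fixation
  falls in the caliper-adjustment interval `[t_box_appear, t_save)`. The value
  on screen at the first look gives the before snapshot; the saved value the
  after.
* **Adjustment classification** — with `d = O − E` (days), a biased
  measurement is adjusted *toward* the expected value when
  `|d_after| < |d_before|`, *away* when the reverse, with a ±0.25-day
  "unchanged" band for display rounding; the signed magnitude is
  `|d_before| − |d_after|`.
* **Cohort statistics** — per-plane incidence tables, paired t/Wilcoxon tests
  of `|d_before|` vs `|d_after|`, a Levene test for the variance reduction
  after the look, repeated-vs-not comparisons, and regressions/ANOVA adjusted
  for maternal BMI and operator experience.
* **Clinical impact** — per scan, the smallest and largest candidate HC, AC
  and FL give the lowest and highest possible EFW (Hadlock three-parameter
  formula); reported as percentage discordance
  `100 · (EFW_max − EFW_min) / EFW_max`, EFW-for-GA Z-score differences, and
  SGA/AGA/LGA reclassification swings (10th/90th centile cutoffs).
* **A synthetic cohort simulator** with known ground truth: operators look at
  the box with probability `p_look` and close a fraction `β` of the `E − O`
  gap after looking, so every stage of the pipeline can be validated and `β`
  recovered.

Growth-standard curves, the EFW formula and the EFW-for-GA reference are a
pluggable coefficient registry (`inst/extdata/growth_standards.yaml`), with
out-of-range measurements extrapolated through the original formula and
flagged, never clamped.

## Worked example

```r
library(scanbias)

sim      <- simulate_cohort(simulation_config(n_scans = 50, seed = 42))
analysis <- analyze_cohort(sim, quiet = TRUE)
analysis
#> Expected-value bias analysis: 50 scans, 173 saved measurements
#>   biased: 91.9%  toward: 72.8%  away: 11.0%  mean adjustment: 2.4 d
#>   EFW discordance: 3.7% +/- 2.7%; Z difference 0.30 +/- 0.22
```

91.9% of the 173 saved measurements were accompanied by a qualifying look at
the measurement box; 72.8% of all saved measurements moved toward the expected
GA against 11.0% away, by 2.4 gestational days on average — the asymmetry that
distinguishes bias from innocent glancing. Between each scan's extreme
candidate measurements the EFW differs by 3.7% on average.

```r
dplyr::select(analysis$incidence, plane, n_saved, per_scan_mean, pct_biased,
              pct_toward, pct_away)
#> # A tibble: 4 × 6
#>   plane n_saved per_scan_mean pct_biased pct_toward pct_away
#> 1 HC         58          1.16       94.8       81.0     6.90
#> 2 AC         53          1.06       94.3       66.0    20.8
#> 3 FL         62          1.24       87.1       71.0     6.45
#> 4 Total     173          3.46       91.9       72.8    11.0

glance(analysis)     # one-row cohort summary
tidy(analysis)       # one row per saved measurement
autoplot(analysis)   # before/after deviation densities per plane

# and the generating bias strength is recovered from the pipeline's output:
parameter_recovery(tidy(analysis), sim$truth, sim$config)
```

Real data enter through the same door: `read_sessions_csv()`,
`read_episodes_jsonl()` and `read_gaze_csv()`, or a single configuration file
driving `run_pipeline()`, which writes `cohort_summary.csv`,
`scan_summaries.csv`, `tests.json`, the figures, and a seed- and
config-hash-stamped metadata record.

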