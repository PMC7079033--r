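---
title: "Quantifying expected-value bias in fetal growth scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying expected-value bias in fetal growth scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanbias)
```

## The problem and the model

Fetal growth is assessed by measuring head circumference (HC), abdominal
circumference (AC) and femur length (FL) on frozen ultrasound planes. While
the operator adjusts the calipers, the machine displays a *measurement box*
with the running value and the gestational age (GA) it corresponds to under
the machine's growth curves. Operators almost always know the pregnancy's
dating GA — the **expected value** `E` (days). Whenever the operator fixates
the measurement box before saving, they acquire the information needed to
nudge the measurement so its **observed value** `O` — the GA implied by the
measurement through a growth-standard curve — moves toward `E`. This package
measures how often that opportunity arises, what it does to the measurements,
and how much the estimated fetal weight (EFW) could differ between the
extreme candidate measurements of one scan.

The analysis works on three tabular inputs per scan session: a gaze stream
(`t_ms`, `x`, `y`, `valid`), a measurement-episode log (plane, measurement-box
rectangle, timestamped value trajectory, save time), and session metadata
(`E`, maternal BMI, operator experience). Video processing and character
recognition sit upstream of this package; we start from extracted event logs.

Key definitions, applied per saved measurement:

* **Fixation**: a gaze dwell on the box rectangle lasting at least 100 ms
  after merging interruptions of at most 400 ms (the conventional lower limit
  for an eye fixation and a standard merge window).
* **Bias event**: at least one fixation inside the caliper-adjustment
  interval `[t_box_appear, t_save)`. The measurement is then *biased*; the
  trajectory value in force at the first fixation's start is the *before*
  snapshot, the saved value the *after*. A measurement with no qualifying
  fixation is *unbiased*. Note this is an opportunity ("risk of bias")
  definition: no caliper motion needs to follow the look.
* **Adjustment class**: with `d = O − E` in days, *toward* if
  `|d_after| < |d_before| − tol`, *away* if `|d_after| > |d_before| + tol`,
  *unchanged* otherwise. The tolerance `tol = 0.25` day absorbs the
  weeks+days rounding of the on-screen GA display and is configurable.
* **Repeat**: any additional saved measurement of a plane already saved in
  the same scan.

### Baseline choice

The before snapshot is the value at the *first look*, not at initial caliper
placement. The first look is the moment the expected-value information
becomes available, so the before/after contrast isolates what knowing the
expected value changes; initial placement is retained in the episode
trajectory for auxiliary analyses.

## Growth standards

All curve knowledge lives in a coefficient registry
(`inst/extdata/growth_standards.yaml`); package logic never hard-codes a
coefficient. The shipped default uses the published Hadlock dating
polynomials (GA in weeks as a polynomial in the measurement in cm), the
Hadlock three-parameter EFW formula

`log10(EFW g) = 1.326 + 0.0107·HC + 0.0438·AC + 0.158·FL − 0.00326·AC·FL`
(all in cm),

and the Hadlock in-utero EFW-for-GA reference
`ln(EFW) = 0.578 + 0.332·w − 0.00354·w²` (`w` = GA in weeks) with a constant
log-scale SD of 0.127 (≈ 12.7 % coefficient of variation). Which curves a
given scanner uses is generally unknowable from the outside, so the registry
makes every choice swappable; the analysis itself is curve-agnostic.

Numerical choices:

* The forward direction (measurement from GA, used by the simulator and for
  round-trip validation) is obtained by root finding (`stats::uniroot`, x
  tolerance 1e-4 mm, far below the 0.01-day equivalent) on the same
  polynomial, so any strictly increasing curve works without an analytic
  inverse. Curve validity (strict monotonicity over the declared GA range) is
  checked at construction.
* Measurements mapping outside a plane's tabulated GA range are
  **extrapolated through the original formula** — mirroring how off-table
  ("OOR") values are computed from the source formula — and flagged, never
  clamped and never dropped. Extrapolation is continuous at the boundary by
  construction.
* SGA/AGA/LGA use 10th/90th EFW centile cutoffs (configurable); a centile
  exactly at a cutoff is AGA (strict inequalities reclassify).
* GA is handled in days throughout; weeks+days only at presentation
  (`format_ga()`).

## Fixation detection semantics

Event logs carry discrete gaze samples, so a sample-to-interval rule is
needed. Each sample covers the interval between the midpoints to its
neighbours; the first and last samples are bounded by their own timestamps.
A sample is in-AOI iff the tracker signal is valid and the point lies inside
the rectangle (boundary inclusive); tracker-loss samples count as out-of-AOI
and their gaps participate in the 400 ms merge rule like any other
interruption. Dwell episodes are clipped to the box's active interval, gaps
≤ 400 ms are merged **first**, and the 100 ms minimum is applied to the
merged span (so 80 ms in, 50 ms away, 80 ms back is one 210 ms fixation).
Merge-then-threshold is the natural reading of "interruption of a fixation";
the order is configurable in effect through the two thresholds.

The test suite checks this algorithm against an independent brute-force
oracle: rasterize the stream onto a fine time grid, attribute every cell
through the same midpoint boundaries, and run-length the in/out sequence.
With integer sample timestamps a 0.5 ms grid makes this comparison exact
rather than approximate.

## The synthetic cohort generator

No raw scan videos or gaze recordings are publicly available, so the package
ships a simulator that emits exactly the input formats the pipeline consumes,
plus a ground-truth table the pipeline never sees. Per scan with expected GA
`E` (uniform over the configured range):

1. each plane's true GA-equivalent is `T = E + δ_scan + ε_plane`,
   `δ ~ N(0, σ_fetal)`, `ε ~ N(0, σ_plane)`;
2. an attempt observes `O₀ = T + η`, `η ~ N(0, σ_meas)`;
3. with probability `p_look` a 150–600 ms box fixation is scripted during
   adjustment and the saved value becomes `O₁ = O₀ + β·(E − O₀) + ν`,
   `ν ~ N(0, σ_adj)`; otherwise `O₁ = O₀`;
4. if `|O₁ − E|` exceeds the repeat threshold τ, another attempt follows with
   probability `p_rep` (same `T`, fresh `η`), up to a small cap.

GA-equivalents are converted to mm through the growth standard's forward
curve, so the bias strength β stays interpretable in days. Gaze streams
contain the scripted fixations, out-of-box wander, short tracker-loss gaps,
and *distractor glances* at the box whose dwell is capped at 80 ms and kept
at least 500 ms clear of any other in-box interval — so neither the 100 ms
threshold nor the 400 ms merge rule can promote them. By construction the
pipeline must recover the scripted look indicators with zero false positives
and zero false negatives, and the tests assert exactly that.

Defaults are fixed once as the study conditions of a routine third-trimester
growth-scan cohort: 272 scans, 16 operators, expected GA 196–280 days,
`σ_fetal = 7`, `σ_plane = 5`, `σ_meas = 4` days (observed−expected spreads of
about 1.5 weeks, the order seen in routine biometry), `p_look = 0.91` (the
observed rate of box looks in routine practice), `β = 0.3` with
`σ_adj = 1` day (mean toward-corrections of the 2–3 day order given those
spreads), `τ = 10` days, `p_rep = 0.7`, 60 Hz gaze, distractor rate 0.1/s.

What the generator deliberately does **not** emulate — and hence what passing
tests do not demonstrate about real data:

* protocol-driven extra measurements (e.g. routinely measuring AC several
  times regardless of its value): repeats here are deviation-triggered only,
  so simulated scans average fewer measurements than a real cohort;
* operator heterogeneity, fatigue or learning: `β` and `p_look` are shared by
  all operators, and the BMI/experience covariates are generated independent
  of the bias mechanism (their adjusted effects are null by design);
* caliper trajectories with many intermediate values, plane-quality issues,
  or any image content;
* real eye-movement dynamics (saccade kinematics, smooth pursuit): fixations
  are scripted rectangles of samples, adequate for AOI-dwell logic, not for
  velocity-based algorithms.

One subtlety worth knowing: because a plane's attempt sequence stops when a
save lands near `E`, episodes that trigger continuation are
disproportionately unlooked, so the marginal fraction of looked episodes sits
slightly below `p_look` (an optional-stopping effect inherent to the model,
not a detection error — detection is exact against ground truth). Tests of
the incidence therefore use binomial bands rather than equality to `p_look`.

## Statistical stage

All statistics operate on the tidy per-measurement record table
(`deviation_records()` / `tidy()`), so every aggregate is reproducible by
hand from one data frame — the tests do exactly that with independent base-R
aggregations.

* Incidence table: per-plane and total saved/repeat counts, measurements per
  scan (mean and SD across scans, zero-counting scans without the plane),
  % biased, % toward, % away, mean ± SD adjustment. Toward/away percentages
  are reported against **both** denominators (all saved measurements, and
  biased ones only), since either convention is defensible; the mean
  adjustment likewise over biased measurements and over all saved ones.
* Paired location tests on `|d_before|` vs `|d_after|`: paired t **and**
  Wilcoxon signed-rank, reported side by side. All-zero difference vectors
  carry no evidence of a shift and report p = 1; degenerate inputs otherwise
  yield explicit `NA` markers rather than errors.
* Variance reduction: Levene's test (median-centered) treating `d_before`
  and `d_after` as two groups, pooled across planes by default with per-plane
  rows alongside.
* Repeated vs not: each saved measurement contributes its own `|d_after|`;
  the default grouping flags measurements after the first of a plane within a
  scan, with a `"series"` alternative (all measurements of multi-measured
  planes) exposed because the convention is genuinely ambiguous.
* Adjusted models: `d_after ~ d_before + bmi + experience_years` among biased
  measurements and an ANOVA of `|d_after|` on repeat status plus covariates;
  missing covariates are dropped listwise with the count logged; zero-variance
  or rank-deficient designs raise explicit singular-design errors.
* EFW impact: per scan, candidate sets per plane are the saved values of all
  episodes plus the first-look values of biased ones (intermediate looks can
  be included by flag, off by default — the before/after two-point reading).
  The smallest/largest candidates give `EFW_min`/`EFW_max`; discordance uses
  the larger EFW as denominator (twin-discordance convention; pairwise mean
  available); swings compare size classes of the two bounds at the expected
  GA. Swing proportions carry Wald intervals by default — the interval that
  reproduces the published example intervals from their counts — with Wilson
  available.
* No multiple-testing correction is applied, mirroring per-comparison
  reporting; the output metadata says so explicitly.
* Bias-strength recovery: under the generative model
  `d_after = (1 − β)·d_before + ν`, the slope of `d_before − d_after` on
  `d_before` among biased measurements estimates β
  (`parameter_recovery()`).

## Validation problem sizes

The shipped suite validates: fixation detection against the rasterization
oracle on 1000 random streams (30–120 Hz, random AOIs, tracker loss); curve
inversion round-trips below 0.1 day on 1000 grid GAs per plane; β recovery
within ±0.1 on a 300-scan cohort at β = 0.5; null calibration (β = 0) of the
paired test at the nominal 5 % level over 100 replicate 40-scan cohorts with
toward/away balance within 5 percentage points at 300 scans; Levene detection
of the variance reduction at 300 scans; and exact agreement of discordance,
Z-differences and swing proportions with brute-force recomputation from
enumerated candidate sets, including the degenerate all-unbiased,
no-repeat cohort where the impact is identically zero.

## Known limitations

* The growth-standard registry ships one default curve family; conclusions
  about a specific scanner require configuring that machine's curves.
* The bias-event definition captures opportunity, not proof, of adjustment;
  the toward/away asymmetry is the evidence that looks are consequential.
* Observed GA deviations conflate true fetal size variation with measurement
  error; the before/after contrast controls for this within a measurement,
  but between-measurement comparisons (repeated vs not) do not.
* The simulator's parameter magnitudes for caliper and plane noise are
  illustrative defaults, not fitted quantities; real-data spreads should be
  checked against them before quantitative transfer.
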