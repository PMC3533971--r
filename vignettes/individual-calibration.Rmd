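---
title: "Individual accelerometer calibration: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual accelerometer calibration: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcal)
```

## The measurement problem

Hip-worn accelerometers report physical activity as "counts", an arbitrary
device unit accumulated per epoch (here 10 s or 60 s) from the vertical
axis. To turn counts into time spent at health-relevant intensities, a
count threshold (cut point) is needed for moderate-to-vigorous physical
activity (MVPA), conventionally defined as at least 3 metabolic
equivalents (METs). Between-subject variation in counts at a given work
rate is the dominant error source in such measurements, and it is
especially pronounced in severely obese adults, whose oxygen cost of
walking is high and whose 3-MET walking speed can lie anywhere between
roughly 1 and 3.5 km/h. `accelcal` implements the full analysis pipeline
for *individual* calibration of the count-to-MET relationship and for
comparing it with a common group-level calibration:

1. **Calibration** (`compute_mets`, `fit_individual`, `derive_icp`,
   `speed_at_met`): per-subject treadmill walking stages (2, 3, 4, 5 and
   6 km/h) give steady-state VO2 and counts/min. METs are individually
   adjusted — stage VO2 divided by the subject's measured resting VO2
   (with the 3.5 ml/kg/min convention available as `mode = "standard"`).
   An ordinary least-squares line `MET = a + b * counts/min` is fitted
   per subject and solved at the 3-MET target for the individual cut
   point (ICP).
2. **Group model** (`fit_group_model`): all subjects' stages are pooled
   in a linear mixed model with a per-subject random intercept and an
   AR(1) covariance over the ordered stages, fitted by REML; the
   fixed-effect line solved at 3 METs gives the group cut point (GCP).
3. **Free-living scoring** (`detect_non_wear`, `classify_mvpa`,
   `detect_bouts`, `summarize_subject`): epoch streams are reintegrated
   to minutes, screened for non-wear and valid days, and tallied into
   MVPA minutes and bouted MVPA under any cut point.
4. **Agreement** (`bland_altman`, `cv_between_methods`,
   `wilcoxon_signed_rank`, `partial_correlations`,
   `polynomial_association`, `guideline_reclassification`): method
   comparison between cut-point sources or sensor placements.
5. **Synthetic data** (`cohort_scenario`, `generate_calibration_cohort`,
   `generate_two_hip_pair`, `freeliving_scenario`,
   `generate_freeliving`, `simulate_group_cohort`): generators with
   known ground truth that stand in for raw study data.

## The individual calibration model

For subject $i$ with resting uptake $V\!O_{2,rest,i}$ and stage
measurements $(V\!O_{2,ij}, c_{ij})$,

$$MET_{ij} = \frac{V\!O_{2,ij}}{V\!O_{2,rest,i}}, \qquad
  MET_{ij} = a_i + b_i c_{ij} + \varepsilon_{ij},$$

fitted by OLS over the (typically five) stages. The fit reports the
Pearson correlation between METs and counts and the standard error of the
estimate, $SEE = \sqrt{RSS/(n-p)}$. The individual cut point is the
3-MET crossing $ICP_i = (3 - a_i)/b_i$.

Two numerical choices matter here:

* **The 100-count floor.** A raw crossing at or below zero counts/min
  would classify *all* wear time as MVPA; such cut points are replaced
  by 100 counts/min and flagged (`floor_applied`). The boundary case
  "exactly zero" is floored too, and a tolerance of $10^{-9}$ counts/min
  absorbs least-squares round-off — nine orders of magnitude below the
  floor itself.
* **Quadratic fits** are implemented (`order = "quadratic"`, cut point =
  smallest positive root) but off by default: with five observations per
  subject a quadratic is prone to overfitting, and the linear form keeps
  individual and group calibrations comparable.

`speed_at_met` reports the treadmill speed at the 3-MET target by
piecewise-linear interpolation of speed against METs. Subjects already
above 3 METs at the slowest stage are extrapolated along the first two
stages (a common situation in this population); results are clamped at
0 km/h. Interpolation was chosen over a per-subject regression of METs
on speed because it makes no linearity assumption across the full speed
range and is exact at the measured stages; the choice is flagged in the
output of the pipeline rather than silently applied.

## The group model

The pooled model is

$$MET_{ij} = \beta_0 + \beta_1 c_{ij} + u_i + e_{ij}, \qquad
  u_i \sim N(0, \sigma^2_u),$$

with AR(1) within-subject residual correlation
$\mathrm{corr}(e_{ij}, e_{ik}) = \rho^{|j-k|}$ over the stage order
(treadmill speed as the repeated measure). Estimation is REML: the fixed
effects are profiled out by generalised least squares, and the profiled
objective is minimised over $(\log\sigma^2_u, \operatorname{atanh}\rho,
\log\sigma^2_e)$ — an unconstrained parameterisation that keeps the
variances positive and $|\rho|<1$ — by Nelder–Mead from three fixed
starting points scaled to the OLS residual variance, guarding against
local optima. Wald 95% intervals use the GLS covariance of the fixed
effects. The estimates agree with `nlme::lme` (random intercept plus
`corAR1`) to full reported precision, and the test suite asserts this
agreement on simulated cohorts.

Degenerate inputs are handled explicitly rather than left to the
optimiser: data that fit a single line exactly make the REML objective
unbounded ($\sigma^2_e \to 0$), so a perfect pooled OLS fit is detected
up front and returned with zero variance components and a warning. An
AR(1) estimate with $|\rho| > 0.99$ raises a boundary warning.

The GCP is $(3-\beta_0)/\beta_1$, reported unrounded and rounded to the
nearest integer count (cut points are applied to integer counts/min in
practice). For the canonical line $MET = 2.5276 + 0.000690\,c$ this is
684.64, i.e. 685 counts/min.

## Free-living scoring rules

All field scoring runs at 60-s resolution after reintegration of 10-s
epochs (the resolution is a knob; reintegration drops and logs trailing
partial blocks rather than zero-padding, which would fabricate wear
time). Days are calendar-aligned, midnight to midnight, and partial
first/last days are screened by the same wear rule as complete days.
Interval outputs use 0-based half-open minute indices.

* **Non-wear**: maximal periods of at least 60 min containing at most 2
  non-zero minutes. The scan is greedy left-to-right: open at a zero
  minute, extend until a third non-zero minute would be included, trim
  trailing non-zero minutes, emit if at least 60 min long. Interruption
  minutes may have any magnitude — no 100-count spike threshold is
  applied, a documented divergence from Troiano-style rules.
* **Valid day / valid measurement**: at least 600 wear minutes per day;
  at least 5 valid days per subject. Per-day outcomes are averaged over
  valid days only.
* **MVPA**: a worn minute with counts/min at or above the cut point.
  The boundary is inclusive because the cut point is the exact solution
  of the calibration line at 3 METs, so the threshold value itself
  attains the target intensity.
* **Bouts**: windows of at least 10 min that start and end on an MVPA
  minute and contain at most 2 below-cut minutes in total (not
  per-interruption, not consecutive-only); bout minutes include the
  allowed drops, and non-wear minutes count against the same allowance.
  The same greedy scan-extend-trim rule is used as for non-wear.

Whether commercial scoring software terminates a bout at the third drop
minute or applies a sliding percentage rule is not documented; the
greedy reading used here is therefore declared, configurable
(`bout_min`, `bout_drop`, `nw_window`, `nw_allowance`), and verified
against an independent brute-force oracle rather than assumed to match
any particular software bit-for-bit. The oracle enumerates *every*
window satisfying the stated rule and tiles greedily from the left; the
test suite checks exact agreement of both detectors with it on 1,000
random 300-minute streams, plus the hand-worked boundary cases (60 vs 59
zeros; 5 MVPA + 2 drops + 5 MVPA = one 12-min bout; 3 drops = none).

## Agreement statistics

For paired measures $x, y$ the differences $d = y - x$ give
$SEM = \mathrm{sd}(d)/\sqrt{2}$ and $LoA = SEM \cdot \sqrt{2} \cdot
1.96$ — algebraically $1.96\,\mathrm{sd}(d)$, an identity the tests
assert on every input. Limits are centred on the median difference by
default (cut-point differences are skewed; the mean is available by
argument). The between-method CV is $100 \cdot \mathrm{sd}(d)$ over the
grand mean of all $2n$ observations — the typical-error convention,
under which pure constant bias contributes nothing; a per-pair variant
sits behind a flag. The signed-rank test uses the exact enumerated null
for up to 25 untied non-zero differences and a tie- and
continuity-corrected normal approximation beyond. Partial correlations
come from the full linear model as $t_j/\sqrt{t_j^2 + df}$, signed like
the coefficient; the single-predictor case collapses to Pearson's r.
Guideline reclassification (default: 30 min/day of bouted MVPA)
reports the 2×2 table, percent agreement and Cohen's kappa with a
normal-approximation p-value. No multiple-testing correction is applied
anywhere; the statistics are reported as-is.

## What the synthetic generators emulate — and what they do not

`generate_calibration_cohort` draws, per subject: resting VO2 from
N(3.04, 0.40) ml/kg/min (truncated at 1.5); a true cut point from
N(1151, 685) counts/min truncated below at 100; a count-per-speed slope
from N(800, 150) counts/min per km/h with counts extrapolating to zero
at 1 km/h; and a MET-per-count slope from N(6.9e-4, 1.2e-4). The
cut-point draw is correlated 0.5 with the resting-VO2 draw, and the
stage VO2 values are back-constructed from the subject's MET line, so
that resting metabolism and walking economy jointly explain most
cut-point variance — qualitatively the structure seen in calibration
studies — without hard-coding any particular partial correlation.
Measurement noise defaults: 0.25 ml/kg/min on stage VO2 (about 3-4% of
a typical walking VO2, the random-error scale of a portable gas
analyser) and 60 counts/min on stage counts. `generate_two_hip_pair`
shares each subject's latent line and VO2 measurements between hips and
adds independent count noise per hip; its default SD (480 counts/min)
was calibrated once, by simulation, so the between-hip cut-point SEM is
about 288 counts/min — the magnitude observed when two devices are worn
on opposite hips — and then frozen.

`generate_freeliving` plans each day at minute resolution: overnight
zeros, a 07:00–22:30 wear window, one planted 75-min daytime non-wear
block, nonzero background activity (uniform between 20 counts/min and
half the smallest candidate cut point) and planted MVPA bouts at 2.5×
the largest candidate cut point, at least 3 background minutes away from
any zero run and from each other. These margins make the truth table
*exact*: wear is precisely the nonzero minutes, every planted bout is
recovered as one bout, and no cut point in the candidate set can flip a
minute. Minutes are then disaggregated uniformly into six 10-s epochs
(counts conserved), so scoring at the 60-s analysis resolution
reproduces the plan bit-for-bit — which the tests and the acceptance
script assert.

What the generators deliberately do **not** emulate: device filtering
and saturation, biomechanically realistic within-minute count texture,
irregular sleep/wake wear schedules, spurious low-count non-wear
interruptions, or seasonal/behavioural day-to-day structure. Passing
the truth-table tests therefore shows the *scoring rules* are
implemented exactly as stated; it does not show how any particular
device behaves on real wear data.

## Validation problem sizes

The shipped test suite runs the detector-oracle equivalence on 1,000
random 300-minute streams; REML parameter recovery on 200 simulated
cohorts of 40 subjects × 5 stages (truth $\beta_0 = 2.5276$,
$\beta_1 = 6.9\times10^{-4}$, $\sigma^2_u = 0.04$, $\rho = 0.5$,
$\sigma^2_e = 0.02$), asserting unbiasedness within 2 Monte-Carlo SEs
and 90–98% Wald coverage; noise-free cut-point recovery to $10^{-6}$
relative on 25-subject cohorts; and exact truth-table fidelity on a
7-day stream at two candidate cut points. These sizes were chosen as
the smallest at which the Monte-Carlo assertions are stable.

## Known limitations

* The AR(1) structure assumes equally spaced stage ranks; unequal speed
  gaps are treated as equal lags, as is conventional when speed is the
  repeated measure.
* Wald intervals (normal quantiles) are used for the fixed effects;
  with 40 subjects the difference from t-based intervals is negligible,
  but with very few subjects coverage will run slightly low.
* The non-wear and bout rules are one declared reading of the standard
  wording; other software may tile interruptions differently. The knobs
  and the oracle make any alternative reading testable.
* `cv_between_methods` implements one of several CV conventions in use;
  results are not comparable across conventions.
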