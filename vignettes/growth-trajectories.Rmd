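---
title: "Modeling growth trajectories under ADHD pharmacotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling growth trajectories under ADHD pharmacotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`growthtraj` implements an observational pharmacoepidemiology workflow for
asking whether ADHD pharmacotherapy — guanfacine monotherapy, guanfacine
adjunctive to a stimulant, or first-line stimulant monotherapy — deflects
children's standardized weight and height trajectories from the reference
norm. This vignette documents the statistical machinery, the choices made
where the design was genuinely open, and what the bundled synthetic-EMR
generator does and does not emulate.

## Standardization: the LMS method

Growth references describe, for each sex and age, the distribution of a
measurement by three parameters: a Box–Cox power $L$, a median $M$, and a
coefficient of variation $S$. A raw value $x$ maps to

$$z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
  z = \frac{\log(x/M)}{S} \quad (L = 0),$$

and `zscore_to_value()` is the exact closed-form inverse. The two branches
join continuously at $L = 0$; the test suite checks continuity at
$|L| = 10^{-8}$ and round-trip identity at $10^{-9}$ relative tolerance.

Choices worth recording:

* **Age arithmetic.** Age in months is days-since-birth × 12/365.25 —
  deterministic and calendar-free, since reference tables are indexed in
  fractional months.
* **Interpolation.** $L$, $M$, $S$ are interpolated linearly and
  independently between the two bracketing grid ages, the standard
  practice for LMS tables; queries at a grid age return the grid row
  exactly.
* **Out-of-range ages.** Patients are followed to age 20 and the 2000 CDC
  charts cover 2–20 years; measurements outside the table's age range are
  dropped with a warning rather than extrapolated.
* **Plausibility screen.** Only z-scores in the inclusive band
  $[-4.5, 4.5]$ enter the analyses; both boundaries are kept.
* **Percentile labels.** Summary tables label a mean z-score with the
  integer percentile `round(100 * pnorm(z))`, rounding halves away from
  zero (0.070 → 53rd, 0.419 → 66th). Labels computed from unrounded
  intermediate estimates can disagree by one ordinal at borderline values;
  the package always labels the value it prints.

## Exposure episodes, prescribed amount and MPR

A prescription covers the closed day interval
`[start_date, start_date + days_supply − 1]`; the drug is assumed taken as
dispensed until exhausted. Coverage intervals of one class merge into
episodes, and an uncovered gap ends the episode — on the last covered day
preceding it — only when it exceeds its seasonal allowance: 30 days during
September–May, 121 days for gaps touching any June–August day (structured
summer drug holidays anchor to the school vacation, so a gap spanning the
boundary takes the summer allowance). Gap length counts uncovered calendar
days strictly between covered days; a prescription starting the day after
another ends creates no gap.

The prescribed amount of one drug at one dose is the *sum of days-supply*
(dispensed supply, not distinct covered days): four 30-day fills are 120
days even if refilled early. Across drug/dose streams of a class, total
supply $T$ is reduced for implausible stockpiling: with $O$ the number of
days covered by more than one distinct stream (counted with multiplicity),
the total prescribed amount is $T - \max(0, O - 90)$ — a single aggregate
90-day cap, deterministic and order-independent. Early refills of the
*same* stream add to $T$ but not to $O$; the convention is recorded here
because dispensing records do not distinguish stockpiling from loss. The
MPR is the prescribed amount during the initial exposure period divided by
the period's length, capped at 1.

Correctness of the interval arithmetic is established against an
exhaustive daily-grid oracle (enumerate every calendar day, apply the
rules literally) on a thousand random prescription sets per run.

## Cohorts and eligibility

The index date is the first in-period (2009-01-01 to 2013-06-30) study
medication — guanfacine or stimulant; atomoxetine is not a study
medication — else the first in-period ADHD diagnosis (ICD-9 314.0,
314.00, 314.01). Eligibility further requires an ADHD diagnosis at any
time, age 4–17 at index (interpreted as [4th birthday, day before 18th
birthday)), EMR history starting at least 12 months before index, a
washout — no guanfacine, stimulant or atomoxetine in the 12 months before
index —, a baseline measurement (the most recent in the 12 months before
time 0) and at least one eligible postbaseline measurement. Weight and
height eligibility are evaluated independently; a patient can contribute
to one analysis only.

Time 0 is the guanfacine initiation date for guanfacine users and the
index date otherwise. Guanfacine users split into subgroups by stimulant
exposure at initiation: **first-line monotherapy** (no stimulant on or
before the first guanfacine fill), **nonfirst-line monotherapy**
(stimulant exposure ended on or before 28 days after it), **combined
pharmacotherapy** (a stimulant fill on the same day, or stimulant coverage
— including refill chains continuing through the allowance rules — running
more than 28 days past it). Patients whose only ADHD medication is
atomoxetine match no cohort definition and are excluded with a distinct
reason. Observation is censored at the earliest of the day before the 20th
birthday, the study end, and the last record in the extract (loss to
follow-up, which the source data model does not define more precisely).

Analysis measurements: the baseline measurement is imputed to time 0;
postbaseline measurements run from time 0 (inclusive) to discontinuation
plus a 60-day tail for medicated cohorts, or to censoring for the
unmedicated cohort, never past censoring. Time is measured in years
(days/365.25).

## The random-coefficients model

For patient $i$ at time $t$ (years from time 0),

$$z_{it} = \mathbf{x}_{it}^\top\beta + b_{0i} + b_{1i}t + b_{2i}t^2 +
  \varepsilon_{it}, \qquad
  \mathbf{b}_i \sim N(0, G),\; \varepsilon_{it} \sim N(0, \sigma^2),$$

with $G$ an unstructured 3 × 3 covariance. Fixed effects per cohort
family: the guanfacine family uses age at baseline, gender (all-patients
stratum only), guanfacine MPR, preguanfacine stimulant prescribed amount,
atomoxetine use before/during exposure, treatment-regimen subgroup
(reference: combined pharmacotherapy) and time × subgroup; the stimulant
family uses age, gender and stimulant MPR; the unmedicated family age and
gender. References: male for gender, "no" for binary covariates.

Estimation is REML through `lme4::lmer`, whose Cholesky parameterisation
keeps $\widehat G$ positive semidefinite by construction; degenerate fits
are reported through a singularity flag rather than a projection step.
Rows are put in a canonical (patient, time) order before fitting so
estimates are invariant to input ordering. $p$-values are nominal,
two-sided, on residual degrees of freedom $n_{\text{obs}} - p$;
small-sample denominator-df approximations (Satterthwaite,
Kenward–Roger) are deliberately out of scope, so printed df should not be
over-interpreted. Missing data are handled by likelihood under the
missing-at-random assumption; no imputation is performed.

Population-level predicted trajectories hold every non-time covariate at
its overall mean in the analysis population — factor covariates at their
observed dummy-column means, i.e. population composition — and, where the
interaction is present, give each subgroup its own time path.

The pre/post model replaces the time trend in the mean by a binary
indicator of whether a measurement was made before or on/after the index
date, keeping random linear and quadratic time; a random intercept is also
included (the conventional choice, and consistent with the main models'
random set). The baseline measurement, imputed at time 0, carries the
"pre" flag; its coefficient is therefore a mean shift *across all time*
and conflates the step change at initiation with any post-initiation
trend — a property inherited from the design, not a bug, and the reason
the trajectory models remain the primary analysis.

## Percentile-shift classification

A clinically notable individual change is a baseline-to-final z-score
shift crossing at least two percentile lines on the chart showing the
5th, 10th, 25th, 50th, 75th, 90th and 95th percentiles (the AACAP
monitoring recommendation). Cutpoints are the standard normal quantiles
of those percentiles; a value lying exactly on a line does not count that
line as crossed (strict betweenness — conservative, and ties are
measure-zero in practice). "At least two" rather than "exactly two" is
used, since a larger shift surely qualifies. The final value is the last
measurement included in the regression; weight and height are classified
independently because their measurement dates need not coincide.

## The synthetic-EMR generator

`simulate_population()` emulates the *structure* the analysis assumes so
that every downstream stage is testable: ADHD diagnosis records, dated
prescriptions with days-supply, refill delays, summer drug holidays,
dose-change streams, regimen layouts matching each cohort definition
(including stimulant chains ending within, or running past, the 28-day
window around guanfacine initiation), renewal-process measurement visits
with a guaranteed baseline-window visit, differential dropout, and
z-scale growth:

$$z(t) = \text{level} + b_{0} + \mathbb{1}[t \ge 0]\left(\delta +
  (\beta_1 + b_{1})t + (\beta_2 + b_{2})t^2\right) + \varepsilon.$$

Generated z-scores are converted to raw kg/cm through the inverse LMS
transform against the active reference table, so the pipeline ingests raw
measurements; standardizing them recovers the generated z to $10^{-9}$.

Default truth parameters are the study conditions the package targets:
declining-then-recovering stimulant-cohort weight
($\beta_1 = -0.7100$, $\beta_2 = 0.2127$ per year on the z scale) and
near-flat unmedicated trajectories ($0.0143$, $-0.0002$); baseline levels
around $+0.07$ to $+0.42$ z-units (treatment-naive children with ADHD run
above the reference median; prior stimulant exposure lowers the level);
initiation shifts $\delta$ of $-0.1346$ (weight) and $-0.0242$ (height)
for stimulants and $+0.0648$ for first-line guanfacine males' weight; ages
4–17 skewed young (guanfacine users youngest); two-thirds male; a regimen
mix dominated by first-line stimulant monotherapy; 30-day fills with
small Poisson refill delays, 25% summer-holiday probability and mean
intended exposure of 250 days; random-effect SDs (0.95, 0.15, 0.05) with
mild negative correlation and residual SD 0.15 — a between-patient
z-score SD near 1, as standardization implies. Annual retention defaults
to 0.5 (medicated) and 0.6 (unmedicated), implemented as independent
censoring; an outcome-dependent dropout mode is intentionally *not* the
default, so parameter-recovery results certify the estimator under MAR,
not robustness to informative dropout.

A synthetic LMS table (smooth sigmoidal median weight ~10→74 kg, height
saturating toward adult stature, $L$ declining from 1.2 to −1, $S$
0.12–0.18 for weight and ≈0.04 for height) stands in for the CDC download
in tests; it is clearly labelled synthetic and any CDC-layout CSV can be
supplied instead. Generated z-scores falling outside the Box–Cox inverse
domain (beyond roughly the 5-SD extreme at the oldest ages) have no raw
counterpart and are dropped — real charts likewise carry no such values.

What the generator does **not** emulate: real health-system demographics,
comorbidity and co-medication structure, visit-frequency dependence on
growth concerns, informative dropout (available only as an explicit
option), dose titration, and pharmacy-level dispensing quirks. Passing
tests therefore certify the *pipeline's rules and estimators*, not the
epidemiology of any particular health system.

## Problem sizes and numerical choices

The test suite runs the generator at 150–500 patients and the
parameter-recovery studies at 1000 patients × 4 visits (trajectory model)
and 2000 patients (pre/post model), sizes at which Monte-Carlo error is
small enough for 3-standard-error recovery checks while a full run stays
comfortably interactive. The acceptance script adds an end-to-end
pipeline run at 1500 patients and a 1000-set daily-grid oracle
comparison. Mixed-model convergence follows `lme4` defaults; singular
fits on tiny strata are reported, not hidden. All randomness flows from a
single integer seed; reruns are bit-identical.

## Known limitations

* Cohorts are modeled separately, so between-cohort contrasts are not
  adjusted for compositional differences (no matching by design).
* Time-varying confounders (co-medications, comorbidities) are not
  modeled; the covariate set is fixed at baseline.
* z-scores outside the reference 3rd–97th percentiles are known to be
  unstable in LMS references generally; the ±4.5 screen removes only
  gross implausibilities.
* Printed degrees of freedom are residual-based; exact small-sample df
  methods are out of scope.
* The pre/post coefficient conflates step and trend (see above).
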