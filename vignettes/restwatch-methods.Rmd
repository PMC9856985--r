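---
title: "Rest-activity rhythms, sleep parameters and penalised survival models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-activity rhythms, sleep parameters and penalised survival models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In advanced cancer, clinicians' survival estimates are known to be
unreliable, and the established prognostic scores (performance status,
inflammatory markers, clinician estimates) leave much of the variance
unexplained. Wrist actigraphy offers a cheap, objective window on a
patient's rest-activity rhythm and sleep, both of which deteriorate with
declining health. `restwatch` implements a complete analysis pipeline for
cohorts of this design: minute-epoch wrist-activity recordings over several
consecutive 24-h periods, a parallel consensus sleep diary, and a routine
clinical table, joined to a right-censored survival outcome and analysed
with regularised Cox models.

Because raw cohorts of this kind are rarely shareable, the package also
contains a first-class synthetic cohort generator with known ground truth;
every statistical claim made by the package's tests is made against that
generator or against brute-force oracles.

## Rest-activity metrics

**Dichotomy index (I\<O).** The percentage of in-bed activity counts
strictly inferior to the median of out-of-bed counts, pooled over the whole
recording. Healthy consolidated sleepers sit near 100%; values at or below
97.5% are conventionally read as a disrupted rest-activity rhythm. Two
conventions needed fixing:

* *"Inferior" is implemented as strictly `<`.* Epochs exactly equal to the
  out-of-bed median do not count. The non-strict variant is available via
  `strict = FALSE` for sensitivity analysis.
* *The out-of-bed median is pooled over the entire recording*, not computed
  per day — this is the published convention for the index. A per-night
  variant (`dichotomy_index_by_night()`) exists for stability analyses
  (day-to-day ICC), where each night's in-bed counts are compared with the
  waking span that precedes it.

A subtlety surfaced by property testing: I\<O is a pure function of count
ranks only when the out-of-bed pool has odd size, because with an even pool
the median is the midpoint of two order statistics and a nonlinear
monotone rescaling of all counts can move an in-bed value across that
midpoint. The package keeps the standard midpoint median; the rank-
invariance tests use odd pools.

The 20-h restricted variant (`restriction = "20h"`) excludes the hour on
either side of every in-bed boundary from both pools before computing,
removing bed-entry and rise transitions. On generated cohorts the 24-h and
20-h variants agree to a rank correlation above 0.95.

**r24.** The Pearson autocorrelation of the count series at a lag of 1440
one-minute epochs (24 h), over pairwise non-missing epochs: day-to-day
reproducibility of the activity profile. It is computed on the raw,
untransformed counts; smoothing or detrending would inflate it and is not
applied. A perfectly periodic profile gives r24 near 1; structureless
counts give r24 near 0.

**MDA and wake activity.** Mean daily activity is the arithmetic mean of
all non-missing epochs. Mean wake activity is the mean over the spans
between consecutive in-bed intervals (strictly between major sleep
periods), pooled.

**Analysis sets.** A "valid 24-h period" is a consecutive 1440-epoch block
with at least 90% non-missing epochs (threshold configurable). Blocks are
aligned to the recording start, not to calendar midnight: wear periods
begin when the device is fitted (typically midday), so midnight alignment
would split every 24-h wear period across two blocks. Eight consecutive
valid periods with a complete diary qualify a participant as
"per protocol"; at least three, "full analysis"; otherwise excluded, and no
rhythm metrics are emitted.

## Sleep scoring and sleep parameters

The device vendor's scoring rule for one-minute epochs is a weighted
five-epoch window,

$$W_t = 0.04\,(c_{t-2}+c_{t+2}) + 0.2\,(c_{t-1}+c_{t+1}) + c_t,$$

with epoch *t* scored sleep when $W_t \le$ the sensitivity threshold
(default 40, the vendor's medium setting; 20 and 80 selectable). Missing
neighbours and neighbours outside the recording contribute zero. Because
the weights are exactly 1/25, 5/25 and 25/25, the package evaluates the
comparison in 25-scaled integer arithmetic, so the tie $W = $ threshold
scores sleep exactly rather than at the mercy of float summation order.

Sleep onset is the start of the first run of at least 10 consecutive
sleep-scored minutes; the final awakening is the end of the last such run
(run length configurable). Between onset and final awakening: TST is the
sleep minutes, WASO the wake minutes, NA the number of contiguous wake
blocks. SOL is the latency from in-bed start to onset, TIB the interval
length, SE = 100·TST/TIB.

**Diary arithmetic.** Per night: TIB = get-up time − bed time, TWAK =
get-up time − final awakening, TST = TIB − (SOL + WASO + TWAK), SE =
100·TST/TIB. Nights whose reported wake components exceed TIB get TST and
SE set missing and are flagged, never clamped to a negative duration. All
clock arithmetic lives on a noon-shifted axis (times before 12:00 get
+24 h, so the axis runs 12:00→36:00) — bedtimes spanning midnight order
correctly and 07:30 encodes as 31.5 decimal hours. Aggregated clock times
use the circular mean (23:30 and 00:30 average to 00:00).

## Feature assembly

The predictor set is declared by a `feature_schema`: name, kind (binary,
ordinal, continuous, clock time), source, ordered levels, and an optional
subjective/objective *twin*. The default schema has 66 predictors:
demographics and opioid use; clinician- and patient-assessed ECOG
performance status at days 0 and 8; modified Glasgow Prognostic Score;
palliative-care prognostic items (clinician survival estimate, global
health status); symptom-burden totals; a 13-analyte blood panel; seven
PSQI component scores, three PSQI disturbance items and two habitual clock
times; twelve actigraphy parameters and eleven diary parameters. The exact
variable list of any given study is configurable through YAML
(`schema_from_yaml()`).

Encoding: binaries → 0/1 by declared level order; ordinals → 0-based
integer ranks respecting the declared ordering (label encoding); clock
times → decimal hours on the noon-shifted axis; continuous pass through.
Imputation is two-stage: a missing value with an observed twin
(actigraphy SE ↔ diary SE, and so on for TST, SOL, WASO, TIB, NA, BT, GUT)
is filled from the participant's own twin first; remaining gaps take the
cohort mean, rounded to the nearest valid rank for ordinals. Any feature
missing in more than 25% of participants (configurable) is an error, and
every imputed cell is logged. Observed values are never altered.
Predictors are standardised inside the model fit (the fitting routine's
default), not in the table, and coefficients are reported on both scales.

## Survival models

Three elastic-net penalised Cox models are fitted, at the mixing
parameters ridge α = 0.01, elastic net α = 0.5 and lasso α = 0.99 (0.99,
not 1.0, is deliberately retained for the lasso setting). The penalty is
α‖β‖₁ + (1−α)/2 ‖β‖₂² on standardised coefficients, maximised along a
100-point log-spaced lambda path from λ_max (all coefficients zero) down
to 10⁻³·λ_max. Lambda is chosen at the minimum mean cross-validated
partial-likelihood deviance (CVM) over 10 folds. Fold assignment is
seeded, stratified by event status so every training set contains events,
and is a function of participant *ids*, not row order — permuting the
input leaves every participant in the same fold.

**Out-of-fold hazards.** For each fold the model is refitted on the other
k−1 folds, with lambda re-selected by an inner cross-validation confined
to those folds, and the held-out participants receive relative hazards
exp(x′β̂) from a model that never saw them. This is the conservative
reading of per-participant blind prediction; the final all-data model and
its in-sample hazards are also returned, clearly labelled, since both
conventions exist in practice. A variable's *selection count* is the
number of fold refits with a nonzero coefficient; "consistently selected"
means selected in all refits.

**Evaluation.** Participants are split at the median out-of-fold hazard
(ties go to the low-hazard group — documented and tested), Kaplan–Meier
curves are estimated per group and compared by the two-group log-rank
test; and the predicted hazard is correlated with observed survival days
by Pearson's r, censored participants entering at their censoring time
(exclusion of censored observations is available as an option).

## Univariate machinery

Kaplan–Meier estimation and the log-rank test wrap the standard
survival-analysis routines (`survfit`, `survdiff`); the log-rank variance
is the usual hypergeometric form with no continuity correction. Split
rules: median (ties low), rank-based quartiles (ties broken by rank order,
groups as equal as possible), and normative cut-offs with their printed
inclusivity — TST ≥ 390 min (6.5 h), SOL ≤ 30 min, SE ≥ 85%, WASO
> 30 min — shipped as the default battery. No multiple-testing correction
is applied across the battery, deliberately; analyses of this design
report unadjusted split p-values, and silently adjusting would change the
published quantity.

Spearman correlations are tie-corrected and banded by magnitude:
negligible < 0.3 ≤ low < 0.5 ≤ moderate < 0.7 ≤ high < 0.9 ≤ very high,
boundaries in the upper band, sign reported separately.

The day-to-day stability of the dichotomy index uses ICC(3,1): two-way
mixed effects, single measure, consistency — days are a fixed set of
"raters" in a stability design, which is why the mixed (not random) model
is the default; ICC(2,1) is selectable. The estimate comes from the
two-way ANOVA mean squares with the standard F-distribution 95% interval.

## The synthetic cohort generator

The generator's defaults are the study conditions: 50 participants, eight
consecutive 24-h periods of one-minute epochs starting at midday, eight
diary nights, 66 predictors, exponential survival with administrative
censoring at day 365.

Each participant has a latent standard-normal frailty *f*. Nights are
scheduled around 23:00–07:30 with Gaussian jitter. Within a night the true
state starts awake (sleep-onset latency ~ Poisson, mean rising with
frailty), ends awake (terminal awakening), and in between is sleep broken
by wake bouts: a bout starts at any sleeping minute with probability
ρ/5 and lasts Geometric minutes (mean 5), so ρ approximates the within-
night wake fraction; ρ rises with frailty over the range 0.05–0.45
(ρ = 0 denotes the fully consolidated sleeper with no in-bed wake at all).
Counts are negative-binomial (size 1.2 — wrist counts are overdispersed):
daytime mean 250·e^(−0.25 f) counts/min modulated by a 24-h sinusoid
peaking mid-afternoon with amplitude falling with frailty, in-bed wake
bouts at 0.9× the daytime mean, sleep at 4 counts/min. The 0.9 factor
matters: nocturnal wake activity must be comparable to the daytime median
for fragmentation to depress I\<O, and with it the generated cohort spans
I\<O ≈ 84–96% with a median near 90% and r24 ≈ 0.14–0.27 — the ranges a
palliative-care cohort of this design actually occupies.

Diaries are the true night structure plus reporting noise (clock times
±10 min sd, durations ±15% cv), with the wake components rescaled when
they would exceed the reported time in bed, so the diary identity holds
after noising. Clinical covariates mix realistic independent draws with
deliberately frailty-correlated ones (CRP, urea, creatinine, neutrophils,
haemoglobin, performance status, PSQI items …), which also supplies the
collinearity the models must handle. Survival times are exponential with
rate λ₀·exp(x′β + 0.5·f) on z-scaled covariates, λ₀ = 1/150 per day —
together with one-year administrative censoring this yields roughly
two-thirds observed events. The default true β is sparse: ten nonzero
coefficients (inflammatory/renal markers and reported sleep disturbance
raising the hazard; haemoglobin, clinician estimate and global health
lowering it).

What the generator does *not* emulate: naps and out-of-bed rest periods,
device artefacts (off-wrist gaps appear only where tests insert them),
non-stationary schedules (shift-like behaviour), seasonal or treatment
effects on survival, and informative censoring. Passing tests therefore
demonstrate correctness of the computations and sensible behaviour under
a realistic data *structure*, not validity on any particular clinical
population. One consequence of the shared frailty: in the synthetic
cohort I\<O genuinely carries prognostic signal, so a univariate I\<O
median split can reach significance there — a property of the generator's
single-factor design, not a claim about patients.

## Numerical and design choices

* Strict `<` against the out-of-bed median; flag to relax.
* Sleep-score threshold comparison in exact integer arithmetic (ties score
  sleep).
* Median splits send ties to the low group, everywhere.
* Fold assignment: seeded, event-stratified, id-keyed.
* λ path 100 points to 10⁻³·λ_max; the automatic path may stop early when
  the deviance saturates, which is why the no-penalty-limit test supplies
  an explicit grid.
* One global seed expands deterministically into per-stage seeds; every
  simulated quantity in the package is a pure function of (spec, seed).
* Missing epochs are explicit NA; zero is a valid count and never a
  missing marker.

Problem sizes used by the test-suite simulations: sparse-recovery at
n = 300, p = 66, 10 true coefficients, 50 replicates; log-rank calibration
over 2000 null two-group draws at n = 40; ICC recovery at 50 subjects × 8
days, 100 replicates; the end-to-end checks run the full 50-participant,
8-day study design, with the strong-signal detection experiment at
three-fold effect sizes over 20 seeds.

## Limitations

Cosinor parameters (mesor, amplitude, acrophase) and nonparametric
circadian statistics (IS/IV) are out of scope, as are native binary device
exports, light/temperature channels, nap detection, competing risks,
time-varying covariates and coefficient confidence intervals. The
imputation is single-value (twin or cohort mean), not multiple; the
schema must be declared, never inferred.
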