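# restwatch

Prognostic modelling for advanced-cancer cohorts from wrist actigraphy,
sleep diaries and routine clinical data.

Patients with advanced cancer show progressively disrupted rest-activity
rhythms and fragmented sleep, and both track declining health. `restwatch`
is an R package for studies that combine three inputs per participant —
minute-epoch wrist-activity counts over several consecutive 24-h periods, a
parallel consensus sleep diary, and a clinical table with a right-censored
survival outcome — and ask whether rhythm, sleep and routine clinical
variables jointly predict survival. It is aimed at biostatisticians and
sleep/circadian researchers working with actigraphy in oncology and
palliative care.

## What it computes

**Rest-activity rhythm metrics.** The dichotomy index

> I\<O = 100 · #{in-bed epochs with count < median(out-of-bed counts)} / #{in-bed epochs},

with I\<O ≤ 97.5% conventionally flagging a disrupted rhythm; a 20-h
restricted variant that drops the hour around each in-bed boundary; the
24-h lag autocorrelation r24; mean daily activity (counts/min); mean
activity during daytime wakefulness; and per-protocol / full-analysis set
qualification (8 vs ≥3 consecutive valid 24-h periods).

**Sleep parameters.** Actiwatch-style sleep/wake scoring of each in-bed
epoch by the weighted window
W = 0.04(c₋₂+c₊₂) + 0.2(c₋₁+c₊₁) + c₀, sleep when W ≤ threshold
(default 40), then per-night BT, GUT, TIB, SOL, TST, SE, WASO and NA from
the scored runs; diary-derived parameters from the identities
TST = TIB − (SOL + WASO + TWAK), SE = 100·TST/TIB, TWAK = GUT − final
awakening, with midnight-aware clock arithmetic and circular averaging.

**Feature assembly.** A schema-driven participants × 66 predictor matrix
(dummy-coded binaries, rank-preserving label encoding for ordinals, clock
times as decimal hours on a noon-shifted axis), twin-first then
cohort-mean imputation with a per-feature missingness cap and a full
imputation log.

**Survival models.** Elastic-net penalised Cox regression (glmnet) at
ridge α = 0.01, elastic net α = 0.5 and lasso α = 0.99, with lambda at the
minimum 10-fold cross-validated partial-likelihood deviance; out-of-fold
relative hazards exp(x′β̂) from fold models blind to the predicted
participant; selection-consistency counts across fold refits;
Kaplan–Meier median-hazard-split log-rank evaluation and the Pearson
correlation between predicted hazard and observed survival.

**Univariate battery and stability.** KM/log-rank with median, quartile
and normative cut-off splits (TST ≥ 6.5 h, SOL ≤ 30 min, SE ≥ 85%,
WASO > 30 min); banded Spearman correlations; ICC(3,1) day-to-day
stability of the dichotomy index.

**Synthetic cohorts.** A seeded generator producing all three inputs with
known ground truth (latent frailty driving fragmentation, daytime
activity, covariates and an exponential survival time), so the whole
pipeline is testable end to end without any patient data.

## Worked example

```r
library(restwatch)

co  <- generate_cohort(cohort_spec(seed = 1))   # 50 participants, 8 days
co
#> <synthetic_cohort> n=50, 8 days, 400 diary nights, 72% events (seed 1)

m <- cohort_metrics(co)
round(summary(m$i_less_o_pct), 1)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    82.6    87.4    89.3    89.6    91.8    96.4

rep <- run_pipeline(cohort = co, seed = 1)
rep
#> <rw_report> n=50, p=66, 36 events
#>   ridge        alpha=0.01 nonzero=61 consistent=49 logrank p=0.778 pearson r=-0.27
#>   elastic_net  alpha=0.50 nonzero=21 consistent= 9 logrank p=0.0988 pearson r=-0.20
#>   lasso        alpha=0.99 nonzero=13 consistent= 4 logrank p=0.47 pearson r=-0.21
```

Reading the report: every participant's I\<O is well below 97.5 (all
rhythms disrupted, as expected in this population); the ridge model keeps
essentially all 66 predictors (61 nonzero, 49 selected in every fold
refit), while the lasso keeps a sparse set of 13. Each model's out-of-fold
hazards are evaluated twice — a median-split log-rank test (can the model
separate shorter from longer survivors it has never seen?) and the Pearson
correlation between predicted hazard and observed days (negative = higher
predicted hazard, shorter survival). On this seed none of the three models
separates the median split significantly, while the univariate dichotomy
index does:

```r
ft <- rep$feature_table
io <- split_and_test(ft$time, ft$event, ft$x[, "i_less_o"], "median")
sprintf("I<O median split: chi-sq %.2f, p = %.3g", io$statistic, io$p)
#> [1] "I<O median split: chi-sq 23.16, p = 1.49e-06"
```

(In the synthetic design a single latent frailty drives both the rhythm
and the hazard, so I\<O is genuinely prognostic there — see the methods
vignette for what the generator does and does not emulate.)

`run_pipeline(..., out_dir = "out")` additionally writes tidy CSVs
(metrics, sleep nights, features + imputation log, univariate battery,
per-model coefficients/hazards/KM coordinates) and a `report.json`
summary. A thin command-line wrapper over the same functions ships at
`inst/scripts/restwatch.R` (`simulate` and `run` subcommands).

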