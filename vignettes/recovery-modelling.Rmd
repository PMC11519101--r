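---
title: "Modelling daily athlete recovery: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily athlete recovery: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wellcast)
```

## The problem

Endurance athletes and their coaches routinely log training sessions
(duration and a session rating of perceived exertion, RPE), dietary intake,
sleep, morning heart-rate variability (HRV) and short wellness
questionnaires. wellcast asks how much of tomorrow morning's *recovery
state* is predictable from these logs, for two outcomes:

* **AM PRS** — the morning Perceived Recovery Status score on the 0–100
  CR100 scale, centered per athlete so a prediction is "points above or
  below this athlete's own average";
* **HRV change** — the day-over-day difference in Ln rMSSD, the natural
  logarithm of the root-mean-square of successive R–R interval
  differences.

The package provides the full workflow: a synthetic cohort generator with
known generative coefficients, feature engineering, lag-based unfolding,
group and individualized predictive models, importance/partial-dependence
interpretation, and a formal comparison of model families.

## Feature engineering

Every workout contributes an internal training load
`TL = duration_min × RPE / 10` (the division by 10 keeps the familiar
session-RPE magnitude despite the 100-point scale). Days aggregate their
sessions by summing duration and load, taking the highest single-session
RPE alongside a duration-weighted mean RPE, duration-weighting the
pre-exercise carbohydrate intake, and flagging the day as fasted-trained if
any session began with less than 5 g of carbohydrate in the pre-exercise
window.

Rolling 7-day measures follow the standard monitoring definitions:
**monotony** = mean daily load / SD of daily load (sample SD, n−1, a choice
this package fixes since conventions differ), **strain** = weekly load ×
monotony, plus the 7-day moving average, 7-day single-day maximum, and an
exponentially weighted moving average with `alpha = 2/(7+1)` seeded at the
first observation (the span-7 convention; the smoothing constant is exposed
in code). The same monotony construction is applied to carbohydrate intake.
The sleep index is sleep duration × subjective sleep quality (h·points).

Three conventions matter and are deliberate:

* **Trailing windows include the current day.** Lagged variants are created
  later by unfolding, so only one windowing convention exists.
* **Rest days count as zero-load days**, not missing ones — monotony is
  only meaningful when easy days lower the weekly mean.
* **Warm-up discipline**: no window statistic is emitted from fewer days
  than its full window; the first six days of each athlete are `NA` (the
  EWMA, being a seeded recursion, runs from day one). A 7-day monotony over
  perfectly uniform loading has zero SD; it is returned as `NA` and later
  imputed like any other gap, which avoids infinite leverage while keeping
  the row.

Day of week enters as seven indicator columns (no ordinal assumption), and
the four planned interaction columns are literal products of their named
parent columns.

## Inclusion, imputation, pruning, unfolding

Athletes are retained if they averaged at least 6 h/week of training,
logged at least 85% of required daily fields, and tracked at least 42 days.
Days whose dietary record is essentially absent are treated as incomplete:
their diet cells are discarded and re-imputed, but the calendar row is kept
so rolling windows never see gapped dates.

Imputation is strictly within athlete: diet and training measures by
k-nearest-neighbour (k = 5) over the athlete's own days on standardized
complete columns, with a linear-regression fallback and finally the
athlete median; all other variables by athlete median. Imputation of raw
logs happens before rolling features are computed; the few derived-feature
gaps that remain (degenerate monotony, warm-up rows) are imputed
afterwards.

Highly correlated predictors (|Pearson r| > 0.85) are then removed
iteratively: find the worst pair, drop the member with the larger mean
absolute correlation against everything else, repeat. This runs **once on
the full unfolded dataset before cross-validation**. That ordering
reproduces the conventional "clean, then model" sequence and is a known,
accepted mild leakage: the set of *columns* (not any fitted parameter) is
chosen using all rows. Pruning is idempotent and deterministic (ties drop
the later column).

**Markov unfolding** turns the per-athlete time series into rows that can
be treated as independent observations: every dynamic column is copied at
lags 1..7 (suffix `_lag1` … `_lag7`) and the first 7 rows of each athlete
are discarded, making the dynamic block 8× wider and each athlete
`n_days − 7` rows long. Unfolding never crosses athlete boundaries. Seven
lags reflect the weekly periodicity of training schedules and is exposed as
a configuration constant, not a fitted quantity. Because 7-day rolling
features appear among the lagged columns, up to 14 days of history reach
the model.

**Same-day availability.** Predicting a *morning* score with that
afternoon's workout would be incoherent, so by default variables measured
at or before the morning observation (sleep, wellness scores, HRV, resting
HR, weekday) may enter at lag 0 while training and diet enter at lags 1–7
only (`same_day = "all"` lifts this for exploratory use). Independently,
same-day copies of the outcome's own measurement family are always
excluded: the centered PRS column for the AM PRS outcome, and every
same-morning HRV *and resting-HR* column for the HRV-change outcome —
resting HR is a readout of the same autonomic state whose change is being
predicted, so its same-day value would leak the answer almost
deterministically.

## Models and validation

Group models are validated by **leave-one-subject-out cross-validation**:
each athlete serves once as the entire test set, hyperparameters are tuned
by an inner CV on the training athletes only, and the reported RMSE/R² are
across-fold means with t-interval 95% CIs from the fold distribution. The
fold-distribution interval (rather than a bootstrap) is this package's
choice where conventions differ; inner rather than outer tuning avoids
optimistic bias. Predictors are standardized with training-fold means/SDs
before penalized fits, and the penalty is chosen at the minimum mean CV
error (not the one-SE rule). R² is the squared Pearson correlation between
observed and predicted, defined 0 for constant predictions — hence exactly
0 for the **intercept-only baseline**, whose LOSO RMSE approximates the
outcome SD and sets the bar every model must beat.

The learner registry covers ridge, lasso and lasso-with-planned-
interactions (glmnet), k-nearest-neighbour regression, an RBF support
vector machine, gradient-boosted trees (xgboost), and a single-layer
neural network; a MARS slot and a second boosting slot exist as adapters
and are skipped with a warning because no backing implementation is
bundled. Regularized linear models are the load-bearing path — in this
problem family the lasso is consistently the strongest performer and
everything downstream (importance, partial dependence) has a fast exact
path for linear fits.

A **random-intercept linear mixed model** on the five highest-importance
features of the group model provides the "tiny model" comparison; under
LOSO the held-out athlete's random effect is unknown and set to zero.

**Individual models** are fit per athlete: every requested learner and
parameter set is scored by repeated k-fold CV (10×10 by default) on that
athlete's rows, the best pair wins (ties to the simpler learner class), and
final accuracy comes from out-of-bag bootstrap resamples (500 by default),
reported as mean ± SD. Two further linear models per athlete use the top
five features of the group model and of the athlete's own model; with an
athlete-level intercept-only baseline these form the model families
compared at the end.

Family comparison fits a linear mixed model (RMSE ~ model type + random
athlete intercept), takes estimated marginal means via emmeans, adjusts all
pairwise contrasts (Sidak by default; Tukey selectable — the two appear
interchangeably in this literature's reporting), and derives a compact
letter display: families sharing no letter differ at α = 0.05. The letter
algorithm covers every non-significant pair with a greedy clique and
absorbs redundant subsets; it is implemented in-package and tested against
the display invariants directly.

## Interpretation

**Permutation importance** is the increase in RMSE after permuting one
feature, averaged over 10 permutations (spread retained for boxplots).
For group models the error is measured on the held-out LOSO predictions —
each row scored by the fold model that never saw its athlete — matching
how out-of-sample importance should be read; for individual models it is
resubstitution on the athlete's own rows. Lagged copies are reported as
distinct features, because "the same variable k days ago" is exactly the
kind of signal this analysis is after.

**Model-based scaled importance** uses |standardized coefficient| for
linear learners (permutation fallback otherwise, negatives truncated),
normalized to sum to 1 so importances can be averaged across athletes whose
chosen algorithms differ; a feature absent from an athlete's model counts
as zero for that athlete.

**Partial dependence** sweeps a feature over 20 grid points spanning its
5th–95th percentile and records the mean prediction with everything else at
observed values; ICE curves are optionally retained. For a linear model the
profile slope equals the raw-scale coefficient — one of the package's
closed-form checks.

## The synthetic cohort: what it emulates and what it does not

No public dataset exists for this design, so the generator is first-class,
tested code. Its defaults describe the study conditions: 43 athletes × 84
days, weekly training periodicity (weekday rest probability ≈ 0.15, long
weekend sessions), habitual volume ~11.8 ± 3.3 h/week, diet means 39.6
kcal/kg, 4.1/1.9/1.7 g/kg CHO/protein/fat, sleep 7.5 ± 0.7 h, and ~2.4%
missing predictor cells (MCAR; only a rate is reported in this literature,
so no informative mechanism is simulated; morning outcome readings are
never blanked).

Ln rMSSD follows a mean-reverting AR(1) around an athlete-specific baseline
(persistence drawn from 0.65–0.85), depressed by the previous day's load
and nudged by sleep; the day-to-day change therefore regresses negatively
on the previous level, with covariate-free lag-1 autocorrelation of the
change equal to `(phi − 1)/2` — a closed form the tests verify by
simulation. Resting HR is a noisy inverse readout of the same state. AM PRS
is the athlete's mean plus deviations driven by soreness, life stress and
sleep quality, with autoregressive persistence at lags 1 *and* 2 — so the
two previous mornings' scores are both genuinely informative, mirroring
the structure this field reports for morning-recovery prediction — clipped
to [0, 100]. The residual SD is steered so centered AM PRS has population
SD ≈ 14.3 unless set explicitly. Wellness integers come from binned latent
Gaussians (soreness 1–10 driven by the last two days' load and sleep;
stress 1–7 as slow AR noise; sleep quality 1–7 from sleep duration): no
distributional form for these instruments is established, so these are
conventions, flagged here. RPE is lognormal-ish clipped to [10, 95]; no
RPE distribution is established either. A "training feeling" column has no
described collection instrument anywhere; it is supported as an optional
pass-through. Body mass is logged weekly — the cadence athletes actually follow — and
forward-filled for daily g/kg normalization (the fill rule is this
package's choice).

A `heterogeneity_sd` switch adds athlete-specific noise to the three
wellness coefficients; with it on, each athlete's truly important features
differ, which turns "individual models beat group models" into a testable
scenario rather than an anecdote. The ground truth object names, per
outcome, the truly predictive variable families: the direct drivers, their
deterministic components and readouts (training load is duration × session
RPE, so both components count; resting HR reads the HRV state out; sleep
quality and the sleep index are readouts of sleep), and generative parents
(training load behind soreness). Variables whose only association with an
outcome is incidental — diet, modality identity, the fasted flag, weekday,
body mass — are never declared drivers, and the importance-recovery checks
test that they stay out of the top ranks.

One structural fact matters for null-cohort reasoning: zeroing every
effect size makes AM PRS pure iid noise (models cannot beat the baseline —
the leakage guard), but the HRV *change* outcome remains predictable from
the previous level for any AR persistence below one, because mean
reversion is built into the process, not carried by an effect size. Null
checks therefore read "no predictability" off the AM PRS outcome.

What the generator does **not** emulate: menstrual-cycle, alcohol or
illness signals (absent from the logs it mimics), device-specific
measurement noise, informative missingness, and nonlinearities or
interactions in the outcome models. Passing tests on this cohort therefore
demonstrate that the pipeline recovers linear-Gaussian structure it was
pointed at — not that real athlete data are this well behaved.

## Numerical and scale choices

Simulation-backed checks run at stated sizes chosen for their statistical
purpose: cohort-level properties use the full 43 × 84 design; replicate
studies use 20 seeded replicates (detection and importance-recovery rates);
the AR(1) closed form uses 10,000 simulated days; inner tuning in replicate
loops uses 3-fold CV over a 20-point penalty path, and glmnet runs with a
1e-5 convergence threshold — coarser than the defaults users get
(`inner_folds = 5`, `nlambda = 50`), which does not change any qualitative
conclusion. Individual-model selection in the comparison study and the
reproduction script uses 5 repeats of 10-fold CV with 50-250 bootstrap
resamples for the lasso stage and 500 resamples for the linear top-five
models whose RMSEs are compared. The pipeline fans a single seed out to every
stochastic stage through fixed offsets, so partial reruns reproduce.

Degenerate inputs are handled explicitly: zero-variance columns are removed
before correlation pruning (their correlations are undefined); a constant
predictor requested for partial dependence is an error; an all-zero
importance vector scales to uniform with a warning; bootstrap resamples
with no out-of-bag rows are redrawn; athletes with too few rows are dropped
from unfolding (≤ 7 rows) or individual modelling (< 30 rows) with
warnings, never silently.

## Known limitations

* The correlation-pruning-before-CV ordering leaks column identity (see
  above); re-running pruning inside every fold would be stricter but
  changes the feature space per fold and is not what practitioners do.
* Group-level HRV-change models see raw Ln rMSSD levels, which confound
  athlete baselines with state; the models partially recover the baseline
  from lagged combinations (level minus its EWMA), but a dedicated
  within-athlete centering of predictors could be explored.
* Bootstrap out-of-bag accuracy for very flexible learners can be
  pessimistic relative to repeated CV; comparisons across model families
  use the same metric everywhere, so rankings are unaffected.
* The CLI surface is the R API: `run_pipeline()` with a `pipeline_config()`
  is the single reproducible entry point, and all artifacts are plain CSV
  and JSON.
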