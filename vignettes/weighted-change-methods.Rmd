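---
title: "Methods: anchor-calibrated weighted change scores and regression trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-calibrated weighted change scores and regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmswc)
```

## The measurement problem

The Hot Flush Rating Scale (HFRS) composite is the mean of three 0–10
severity domains (distress, problems, disruption to daily life). A couplet
pairs a baseline questionnaire with a six-week follow-up; the raw change is
`C = X2 − X1`, so negative change is improvement. A fixed change threshold
treats a 2-point drop the same for a patient who started at 3 and one who
started at 9, yet patients with little symptom burden at baseline have
little perceptible room to improve. Evidence from chronic-pain outcomes
suggests perceived benefit depends on both baseline severity and the
direction of change, and the same pattern is plausible for vasomotor
symptoms.

## The weighted change score

The package models the dependence with a logistic weight of baseline
severity,

$$w(X_1) = \frac{1}{1 + e^{-(b_0 + b_1 X_1)}}, \qquad C' = w(X_1)\,C,$$

fitted **separately for the improvement stratum (`C < 0`) and the
non-improvement stratum (`C ≥ 0`)**. Zero change sits in the
non-improvement stratum by definition and contributes `C' = 0`. The weight
is strictly inside (0, 1), so weighting can never flip the direction of a
change nor inflate its magnitude; with `b1 > 0` it grows with baseline
severity, down-weighting changes reported from low baselines. Numerically,
`w` saturates to 1.0 in double precision once `b0 + b1·X1` exceeds about
36; within the default search box and the 0–10 severity range this only
occurs at the extreme corner of the box.

### Calibration against the effectiveness anchor

The anchor is a 5-level Likert item ("my treatment adequately controls my
VMS"), coded 1 (strongly disagree) to 5 (strongly agree), with "not
applicable" coded as neutral (3). Within each stratum, `(b0, b1)` is chosen
to maximize the Spearman correlation (mid-rank ties) between `C'` and the
anchor, over the box `b0 ∈ [−10, 0]`, `b1 ∈ [0, 5]`. Only couplets with a
complete composite at both time points *and* an anchor response enter the
fit; couplets with an anchor but an incomplete composite are excluded from
every analysis.

Two conventions were genuinely open and are exposed as arguments:

* **Objective sign.** The default maximizes `|ρ(C', anchor)|`
  (`objective = "abs_max"`), so one criterion serves both strata whatever
  the anchor's orientation; `"signed_max"` is available where the
  orientation is known a priori.
* **Degenerate curves.** A candidate `(b0, b1)` that collapses `C'` to a
  constant (possible at the extreme corner of the box where every weight
  underflows) is scored −1 rather than raising an undefined-correlation
  error inside the optimizer.

Because `w` is constant when `b1 = 0`, `C'` is then a positive multiple of
`C` and the weighted correlation equals the raw correlation *exactly*: the
raw change score is a point inside the search space, so the fitted
objective can never fall below the raw objective by more than the
optimizer's tolerance. This rank-preservation identity is the core safety
property of the method and is asserted exactly in the tests.

## The Bayesian optimizer

Both the weight calibration and the tree tuning use the same bounded
maximizer: per repeat, 20 Latin-hypercube evaluations of the objective,
then GP-guided acquisitions choosing the candidate maximizing the upper
confidence bound (posterior mean + κ·sd, κ = 2.576); 10 independent
repeats, overall best reported. The GP uses a Matérn 5/2 kernel on inputs
normalized to the unit box, a profiled signal variance, a small
length-scale grid selected by marginal likelihood, and observation jitter
1e-6 (objectives are deterministic; callers with stochastic objectives fix
their own internal seeds). The acquisition argmax is taken over a fresh
uniform candidate set plus local perturbations of the incumbent, so the
returned optimum is always a point that was actually evaluated. Integer
dimensions are optimized on a continuous relaxation and rounded at
evaluation time. The "repeats" are independent restarts (each reseeded as
`seed + r − 1`), which makes a longer iteration budget a strict superset of
a shorter one on the same seed — the package's monotone-budget guarantee.
The per-repeat count of GP-guided iterations is not fixed by the study
protocol; the package default is 25.

## The regression tree

The tree response is the weighted change score; predictors are the six
variables of the modelling design: days between questionnaires
(dichotomized at 56 days — the six-week follow-up plus the two-week
reminder window), intervention category (5 levels, never missing), age
(three bands, default <50 / 50–59 / ≥60: round-decade cuts bracketing the
cohort's median age, configurable), adherence days (continuous),
menopausal status (2 levels), and endocrine-therapy duration (dichotomized
at 12 months, when symptoms are typically most severe). A variance
inflation factor screen (`1/(1−R²)` per dummy-encoded column, advisory
threshold 5) is reported before modelling.

Fitting is CART with the `rpart` engine: variance-reduction splitting,
exhaustive binary partition search over categorical levels, `minsplit` /
`minbucket` / depth constraints, and the rpart `cp` convention (a split
must improve the root-deviance-scaled error by at least `cp`). Depth is
counted with the root at level 1, i.e. one less than this package's
`max_depth` in rpart's root-at-0 units. Rows missing a split variable are
routed by the best agreeing surrogate, falling back to the majority
direction. One engine behaviour worth knowing: a *factor* surrogate whose
split ties the primary split as a competitor is not retained by rpart, so
a perfectly duplicated factor column will not appear in the surrogate
list, while a perfectly separating continuous surrogate will.

Terminal nodes report the median member response with a 95% bootstrap
percentile interval (2000 seeded resamples of the median). The bootstrap
was chosen because the terminal-node interval definition was open; leaf
*point predictions* remain the mean, keeping MSE evaluation coherent,
while the median is the display statistic. Leaves with fewer than two
distinct members report the degenerate interval [median, median].

## Nested cross-validation

Generalization error comes from ten outer folds (simple random assignment,
no stratification). Within each outer training set, five-fold CV MSE is
minimized over the hyperparameter box — parent node 5–20, terminal node
2–10, `cp` 0.001–0.1, depth 3–7 — by the Bayesian optimizer on the negated
MSE; the inner fold assignment is fixed per outer fold so the objective is
deterministic. Candidate points with `min_terminal > min_parent` are
clamped to respect the nesting at evaluation. The tuned tree is refit on
the outer training set and scored on the held-out fold; no test row ever
informs its own hyperparameters. The reported MSE is the mean of the ten
outer-fold MSEs with interval mean ± 1.96·sd/√10 (the interval definition
is stated explicitly because it was open). The final displayed model is
refit on all rows with the modal per-fold hyperparameters, ties broken by
the lowest `cp` — a deliberate bias toward the least complex of the tied
choices.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the scale of the cohort it models: baseline severity latent Beta(1.80,
1.74) scaled to 0–10 (quartiles 3.24 / 5.10 / 6.94, matching the target
median 5.0 and IQR 3.3–7.0), three baseline domains jittered around the
latent severity (sd 0.7, clipped to 0–10), intervention mix
27/25/11/8/29%, arm effects −1.0 / −1.6 / −1.2 / −1.0 / −0.2 HFRS points
(CAM the largest improvement, controls near zero) with change noise sd
1.5 — yielding roughly 70–75% improvement among complete couplets — and
covariates calibrated to the reported cohort quantiles (median age ≈52,
≈38 VMS/week, ≈9.9 months of endocrine therapy, ≈54.5 days between
questionnaires, ≈51% pre/perimenopausal). Follow-up domains are
reverse-engineered from the composite change (target composite plus
per-domain noise, re-clipped), since only the composite is modelled. The
anchor is generated from a **known** weight curve — latent effectiveness
`−C'_true + N(0, 0.8)` thresholded at (−0.75, 0.25, 1.25, 2.5) — so
parameter recovery is testable; 27% of couplets lose their follow-up and
27% their anchor, independently.

What the generator does *not* emulate: informative missingness (loss to
follow-up independent of severity), within-patient correlation for repeat
participants (couplets are analysed as independent rows, as the analysis
assumes), measurement drift between questionnaires, and any placebo
structure. Passing tests therefore demonstrate that the machinery recovers
known structure under the stated noise model — not that the clinical
findings generalize.

## Numerical and scale choices

Tolerances in the recovery tests (fitted objective within 0.02 of the
truth's; weight-curve Spearman > 0.9 in at least 18 of 20 replicate
cohorts of 300) mirror the optimizer's resolution on its default box. The
test and pipeline runs use reduced optimizer budgets (e.g. 6–15 initial
points, 1–2 repeats, 4–10 iterations) and cohorts of 100–300 couplets —
sizes at which every qualitative property is already stable — while the
package defaults keep the full protocol (20 points, 10 repeats, κ =
2.576). `generate_known_tree_cohort()` returns the derived predictor/
response pair directly rather than a raw questionnaire table: its region
means live on the derived predictor levels, and reconstructing raw domains
would reintroduce scoring noise into oracles that need exact error floors.

## Known limitations

Calibration and tree modelling on the same data can bias apparent model
performance; the package mirrors that design (the weights fitted on the
anchor-complete subset are applied to all complete couplets) and the
nested CV only protects the hyperparameter selection. Small strata make
the fitted betas sit on the box edge (`b0 = −10` is a boundary optimum,
here as in the cohort the defaults emulate); widening the box is a
one-argument change but was not the protocol. The absolute-correlation
objective cannot distinguish an anchor that reverses orientation between
strata from a sign error in the data — inspect `rho_raw` signs before
interpreting fitted curves.
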