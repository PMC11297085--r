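# vmswc — anchor-calibrated weighted change scores for vasomotor symptoms

Vasomotor symptoms (VMS — hot flashes and night sweats) are common during
breast-cancer endocrine therapy, and trials of VMS interventions are hard to
compare because a fixed minimal clinically important difference ignores two
things patients clearly feel: how severe their symptoms were to begin with,
and whether symptoms are improving or deteriorating. `vmswc` implements a
weighted change score for the Hot Flush Rating Scale (HFRS) composite
(the mean of three 0–10 severity domains) that encodes both.

For a survey couplet with baseline composite `X1` and six-week follow-up
`X2`, the raw change is `C = X2 − X1` and the weighted change is

```
C' = w(X1) · C,      w(X1) = 1 / (1 + exp(−(b0 + b1·X1)))
```

with `(b0, b1)` fitted **separately for the improvement stratum (C < 0) and
the non-improvement stratum (C ≥ 0)** by Gaussian-process Bayesian
optimization (upper-confidence-bound acquisition, κ = 2.576), maximizing the
Spearman correlation between `C'` and a 5-level patient-reported
treatment-effectiveness anchor. Downstream, the weighted change score is
modelled with a CART regression tree (surrogate splits for missing
predictors) whose hyperparameters are tuned by ten-fold nested
cross-validation with an inner five-fold Bayesian-optimization loop.

The package is aimed at biostatisticians analysing patient-reported outcome
couplets: it ships the scoring rules, the calibration machinery, the tree
pipeline, descriptive cohort statistics, and a calibrated synthetic cohort
generator so the entire analysis is runnable and testable without
patient-level data.

## Worked example

A patient with baseline HFRS 6 under the improvement-stratum parameters
(b0 = −10, b1 = 2.68) keeps essentially the whole of a 3-point improvement;
a low-baseline patient at weight 0.6 needs a 3.3-point raw reduction to
register a weighted change of 2:

```r
library(vmswc)
p <- weight_params(-10, 2.68, "improvement")
sigmoid_weight(6, p)
#> [1] 0.997717          # rounds to 1: a 3-point raw change stays ~3 points
required_raw_change(2, 0.6)
#> [1] 3.333333          # ~3.3 raw points for 2 weighted points at w = 0.6
```

End to end on a synthetic cohort:

```r
co  <- generate_cohort(generator_config(n_couplets = 100, seed = 7))
rec <- change_records(co)            # 72 complete couplets, 51 improved
fit <- fit_weight_params(rec, "improvement",
                         opt = bo_config(n_init_points = 15, n_repeats = 2,
                                         n_iterations = 10, seed = 7))
fit$report[c("n", "b0", "b1", "rho_raw", "rho_weighted")]
#> $n 42          # couplets with complete outcome + anchor in the stratum
#> $b0 -10        # fitted intercept (box edge, as in the cohort it emulates)
#> $b1 2.55       # fitted slope per HFRS unit
#> $rho_raw -0.534      # Spearman of raw change vs anchor
#> $rho_weighted -0.713 # weighting strengthens the anchor correlation
```

Baseline weighting strengthens the anchor correlation because couplets with
low baseline severity — whose raw changes the anchor barely registers — are
shrunk toward zero. The one-command pipeline writes every stage (cohort CSV,
change records, fitted weights, weighted scores, VIF screen, nested-CV
report, tree JSON + text diagram, manifest with checksums):

```r
run_pipeline(run_config(out_dir = "runs/demo",
                        generator = generator_config(n_couplets = 100, seed = 7),
                        seed = 7))
```

A shell wrapper lives at `inst/cli/vmswc.R`
(`Rscript inst/cli/vmswc.R run --n 100 --seed 7 --out runs/demo`).

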