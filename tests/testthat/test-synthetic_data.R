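test_that("the generator honours trivial and determinism contracts", {
  expect_equal(nrow(generate_cohort(generator_config(n_couplets = 0))), 0L)
  c1 <- generate_cohort(generator_config(n_couplets = 50, seed = 13))
  c2 <- generate_cohort(generator_config(n_couplets = 50, seed = 13))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_error(generator_config(intervention_probs = c(
    lifestyle = 0.5, cam = 0.5, drug = 0.5,
    endocrine_modification = 0, control = 0)))
})

test_that("large cohorts hit the configured calibration targets", {
  co <- generate_cohort(generator_config(n_couplets = 5000, seed = 101))
  X1 <- rowMeans(co[, c("b_dom1", "b_dom2", "b_dom3")])
  q <- quantile(X1, c(0.25, 0.5, 0.75), names = FALSE)
  rel <- function(got, want) abs(got - want) / abs(want)
  expect_lt(rel(q[2], 5.0), 0.1)
  expect_lt(rel(q[1], 3.3), 0.1)
  expect_lt(rel(q[3], 7.0), 0.1)
  expect_lt(rel(median(co$age_years), 52), 0.1)
  expect_lt(rel(median(co$vms_per_week), 38), 0.1)
  expect_lt(rel(median(co$et_months), 9.9), 0.1)
  expect_lt(rel(median(co$days_between), 54.5), 0.1)
  expect_lt(rel(mean(is.na(co$likert)), 0.27), 0.1)
  expect_lt(rel(mean(is.na(co$f_dom1)), 0.27), 0.1)
  mix <- table(co$intervention)[c("lifestyle", "cam", "drug",
                                  "endocrine_modification", "control")]
  expect_lt(max(abs(mix / 5000 - c(0.27, 0.25, 0.11, 0.08, 0.29))), 0.03)
})

test_that("with no anchor noise the anchor latent is a monotone image of C'", {
  cfg <- generator_config(n_couplets = 300, seed = 23, anchor_noise_sd = 0)
  co <- generate_cohort(cfg)
  truth <- attr(co, "truth")
  expect_equal(spearman_rho(truth$C_prime, truth$latent), -1)
})

test_that("known-tree cohorts enforce region structure", {
  single <- generate_known_tree_cohort(
    30, regions = list(list(when = list(), mean = 1.5)), seed = 1)
  expect_equal(single$y, rep(1.5, 30))

  overlapping <- list(
    list(when = list(intervention = c("cam", "drug")), mean = 1),
    list(when = list(intervention = c("drug", "control",
                                      "lifestyle",
                                      "endocrine_modification")), mean = 0))
  expect_error(generate_known_tree_cohort(50, overlapping, seed = 2),
               "overlapping")
  gappy <- list(list(when = list(intervention = "cam"), mean = 1))
  expect_error(generate_known_tree_cohort(50, gappy, seed = 2),
               "cover")
})

test_that("a noiseless two-region cohort is recovered exactly by the tree", {
  kt <- generate_known_tree_cohort(
    150, regions = list(
      list(when = list(intervention = c("cam", "drug")), mean = 4),
      list(when = list(intervention = c("lifestyle",
                                        "endocrine_modification",
                                        "control")), mean = 0)),
    noise_sd = 0, seed = 5)
  tree <- grow_tree(kt$x, kt$y, tree_hyperparams(10, 4, 0.01, 4))
  expect_equal(predict(tree, kt$x), kt$y)
  expect_equal(sum(tree$fit$frame$var == "<leaf>"), 2L)
})

test_that("weighting beats the raw change score across generator seeds", {
  wins <- 0L
  for (seed in 1:20) {
    co <- generate_cohort(generator_config(n_couplets = 150, seed = seed))
    rec <- change_records(co)
    fit <- fit_weight_params(rec, "improvement", opt = small_bo(seed))
    sub <- rec[rec$stratum == "improvement" & !is.na(rec$anchor), ]
    raw_obj <- abs(spearman_rho(sub$C, sub$anchor))
    if (fit$report$best_value >= raw_obj - 0.02) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
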