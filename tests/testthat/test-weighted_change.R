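test_that("the logistic weight hits its midpoint and stated examples", {
  p <- weight_params(-10, 2.68)
  # midpoint: w = 0.5 exactly at X1 = -b0/b1
  expect_equal(sigmoid_weight(-p$b0 / p$b1, p), 0.5)
  expect_equal(sigmoid_weight(0, weight_params(0, 1)), 0.5)
  # high-baseline patient: weight ~0.998, rounds to 1
  expect_equal(round(sigmoid_weight(6, p)), 1)
  expect_error(sigmoid_weight(11, p), "outside")
  expect_error(weight_params(Inf, 1), "finite")
})

test_that("weights stay in (0,1), monotone in X1 with the sign of b1", {
  set.seed(7)
  X1 <- sort(runif(50, 0, 10))
  for (i in 1:20) {
    b0 <- runif(1, -10, 0)
    b1 <- runif(1, 0.05, 2.9)   # keeps |b0 + b1*X1| well inside double range
    w <- sigmoid_weight(X1, weight_params(b0, b1))
    expect_true(all(w > 0 & w < 1))
    expect_true(all(diff(w) > 0))
  }
  # b1 = 0: constant weight
  w0 <- sigmoid_weight(X1, weight_params(-2, 0))
  expect_true(all(w0 == w0[1]))
})

test_that("weighted change preserves sign and never inflates magnitude", {
  params <- list(improvement = weight_params(-10, 2.68, "improvement"),
                 non_improvement = weight_params(-9.45, 1.27,
                                                 "non_improvement"))
  co <- generate_cohort(generator_config(n_couplets = 150, seed = 21))
  rec <- change_records(co)
  wc <- weighted_change_score(rec, params)
  expect_equal(wc$C_prime, wc$w * wc$C)
  expect_true(all(sign(wc$C_prime) == sign(wc$C)))
  expect_true(all(abs(wc$C_prime) <= abs(wc$C)))
  # worked values: a 3-point improvement at baseline 6 keeps ~3 points
  one <- data.frame(couplet_id = "a", X1 = 6, X2 = 3, C = -3,
                    stratum = factor("improvement",
                                     levels = levels(rec$stratum)),
                    anchor = 5L)
  expect_equal(round(abs(weighted_change_score(one, params)$C_prime)), 3)
  zero <- one; zero$C <- 0; zero$X2 <- 6
  zero$stratum <- factor("non_improvement", levels = levels(rec$stratum))
  expect_equal(weighted_change_score(zero, params)$C_prime, 0)
  expect_error(weighted_change_score(one, params["non_improvement"]),
               "no weight parameters")
})

test_that("required raw change inverts the weighting", {
  expect_equal(round(required_raw_change(2, 0.6), 1), 3.3)
  expect_equal(required_raw_change(0, 0.37), 0)
  expect_equal(required_raw_change(1, 1), 1)
  expect_error(required_raw_change(2, 0), "\\(0, 1\\]")
  expect_error(required_raw_change(2, -0.1), "\\(0, 1\\]")
})

test_that("Spearman matches a brute-force mid-rank oracle, ties included", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(2, 1, 3, 4)),
               oracle_spearman(c(1, 2, 2, 4), c(2, 1, 3, 4)))
  set.seed(11)
  for (i in 1:25) {
    a <- sample(1:5, 12, replace = TRUE)
    b <- sample(1:8, 12, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("a zero slope preserves ranks exactly", {
  rec <- make_stratum_records(80, weight_params(-10, 2.68), seed = 5)
  p0 <- list(improvement = weight_params(-3, 0, "improvement"))
  wc <- weighted_change_score(rec, p0)
  expect_equal(spearman_rho(wc$C_prime, rec$anchor),
               spearman_rho(rec$C, rec$anchor))
})

test_that("calibration recovers a strong anchor relationship", {
  truth <- weight_params(-10, 2.68, "improvement")
  rec <- make_stratum_records(300, truth, anchor_noise_sd = 0.5, seed = 2)
  fit <- fit_weight_params(rec, "improvement",
                           opt = bo_config(n_init_points = 15,
                                           n_repeats = 2,
                                           n_iterations = 10, seed = 4))
  obj_at <- function(p) {
    cp <- sigmoid_weight(rec$X1, p) * rec$C
    abs(spearman_rho(cp, rec$anchor))
  }
  # fitted objective is at least the truth's, minus optimizer tolerance
  expect_gte(fit$report$best_value, obj_at(truth) - 0.02)
  # and at least the raw-equivalent (b1 = 0) objective
  expect_gte(fit$report$best_value,
             obj_at(weight_params(-1, 0, "improvement")) - 0.02)
})

test_that("an uninformative anchor yields a weak fitted correlation", {
  rec <- make_stratum_records(200, weight_params(-10, 2.68), seed = 8)
  set.seed(9)
  rec$anchor <- sample(1:5, nrow(rec), replace = TRUE)   # pure noise
  fit <- fit_weight_params(rec, "improvement", opt = small_bo(3))
  expect_lt(abs(fit$report$rho_weighted), 0.35)
})

test_that("degenerate calibration inputs raise informative errors", {
  rec <- make_stratum_records(3, weight_params(-10, 2.68), seed = 1)
  expect_error(fit_weight_params(rec, "improvement"), "insufficient data")
  rec5 <- make_stratum_records(20, weight_params(-10, 2.68), seed = 1)
  rec5$anchor <- 3L
  expect_error(fit_weight_params(rec5, "improvement"), "constant")
})
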