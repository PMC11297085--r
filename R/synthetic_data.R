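## Synthetic cohort generator -------------------------------------------
##
## Emulates the statistical structure the analysis assumes: a baseline
## severity distribution matching the reported cohort quantiles, five
## intervention arms with calibrated uptake and effect sizes, a
## treatment-effectiveness anchor generated from a KNOWN weight curve
## (so parameter recovery can be tested), and realistic missingness.

#' Synthetic cohort configuration
#'
#' Defaults are calibrated to the study cohort this package models:
#' baseline HFRS composite with median 5.0 and IQR 3.3-7.0 (latent
#' Beta(1.80, 1.74) scaled to 0-10), about 38 VMS per week, intervention
#' mix 27/25/11/8 per 100 couplets with 29 controls, 27% anchor
#' missingness and 27% loss to follow-up, median age 52, median 9.9
#' months of endocrine therapy, and a median of 54.5 days between
#' questionnaires. The anchor is a noisy monotone function of the TRUE
#' weighted change computed with `true_weight_params`, thresholded to
#' the 5-level Likert scale.
#'
#' @param n_couplets Number of survey couplets.
#' @param seed Integer seed.
#' @param baseline_shape1,baseline_shape2 Beta shapes of the latent
#'   baseline severity (scaled to 0-10).
#' @param domain_noise_sd SD of per-domain noise around the composite
#'   (scores clipped to 0-10).
#' @param intervention_probs Named probabilities over the five arms.
#' @param effect_by_intervention Named mean raw six-week change per arm
#'   (negative = improvement; CAM largest by default).
#' @param change_noise_sd SD of the raw change around the arm effect.
#' @param true_weight_params List of [weight_params()] per stratum used
#'   to generate the anchor.
#' @param anchor_scale,anchor_noise_sd Latent effectiveness is
#'   `-anchor_scale * C_true' + N(0, anchor_noise_sd)`.
#' @param anchor_thresholds Four increasing cut points mapping the
#'   latent effectiveness to Likert levels 1-5.
#' @param missing_anchor_rate,lost_to_followup_rate Independent
#'   missingness rates for the anchor and the follow-up questionnaire.
#' @param repeat_patient_rate Fraction of couplets contributed by a
#'   patient who already contributed one.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_couplets = 100L, seed = 20210903L,
                             baseline_shape1 = 1.80,
                             baseline_shape2 = 1.74,
                             domain_noise_sd = 0.7,
                             intervention_probs = c(
                               lifestyle = 0.27, cam = 0.25, drug = 0.11,
                               endocrine_modification = 0.08,
                               control = 0.29),
                             effect_by_intervention = c(
                               lifestyle = -1.0, cam = -1.6, drug = -1.2,
                               endocrine_modification = -1.0,
                               control = -0.2),
                             change_noise_sd = 1.5,
                             true_weight_params = list(
                               improvement = weight_params(-10, 2.68,
                                                           "improvement"),
                               non_improvement = weight_params(
                                 -9.45, 1.27, "non_improvement")),
                             anchor_scale = 1,
                             anchor_noise_sd = 0.8,
                             anchor_thresholds = c(-0.75, 0.25, 1.25, 2.5),
                             missing_anchor_rate = 0.27,
                             lost_to_followup_rate = 0.27,
                             repeat_patient_rate = 0.12) {
  stopifnot(n_couplets >= 0,
            abs(sum(intervention_probs) - 1) < 1e-8,
            all(intervention_probs >= 0),
            setequal(names(intervention_probs), intervention_levels()),
            setequal(names(effect_by_intervention), intervention_levels()),
            all(diff(anchor_thresholds) > 0),
            length(anchor_thresholds) == 4L,
            missing_anchor_rate >= 0, missing_anchor_rate <= 1,
            lost_to_followup_rate >= 0, lost_to_followup_rate <= 1,
            domain_noise_sd >= 0, change_noise_sd >= 0,
            anchor_noise_sd >= 0)
  structure(as.list(environment()), class = "generator_config")
}

.clip01 <- function(v, lo = 0, hi = 10) pmin(pmax(v, lo), hi)

#' Generate a synthetic cohort
#'
#' Per couplet: a latent baseline severity drawn from the scaled Beta
#' distribution is jittered into three baseline domain scores; an
#' intervention arm is assigned; a raw six-week change (arm effect plus
#' Gaussian noise) produces follow-up domains consistent with
#' X2 = X1 + change after clipping to 0-10; the TRUE weighted change is
#' computed from `true_weight_params` at the realized baseline and
#' change, and a noisy monotone transform of it is thresholded into the
#' Likert anchor. Loss to follow-up blanks the follow-up domains and
#' anchor missingness blanks the Likert response, independently.
#'
#' @param config A [generator_config()].
#' @return A validated `vms_cohort` data frame.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(config$n_couplets)
  cols <- cohort_columns()
  if (n == 0L) {
    empty <- as.data.frame(stats::setNames(
      lapply(cols, function(cl)
        if (cl %in% .numeric_cols()) numeric(0) else character(0)), cols))
    return(validate_cohort(empty))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed %% .Machine$integer.max)

  # patients: a fraction of couplets repeat an earlier patient
  n_patients <- max(1L, ceiling(n * (1 - config$repeat_patient_rate)))
  patient_idx <- c(seq_len(min(n, n_patients)),
                   if (n > n_patients)
                     sample.int(n_patients, n - n_patients, replace = TRUE))

  S <- 10 * stats::rbeta(n, config$baseline_shape1, config$baseline_shape2)
  bdom <- vapply(1:3, function(j)
    .clip01(S + stats::rnorm(n, 0, config$domain_noise_sd)), numeric(n))
  X1 <- rowMeans(bdom)

  arm <- sample(intervention_levels(), n, replace = TRUE,
                prob = config$intervention_probs[intervention_levels()])
  change <- config$effect_by_intervention[arm] +
    stats::rnorm(n, 0, config$change_noise_sd)
  X2_target <- .clip01(X1 + change)
  fdom <- vapply(1:3, function(j)
    .clip01(X2_target + stats::rnorm(n, 0, config$domain_noise_sd)),
    numeric(n))
  X2 <- rowMeans(fdom)
  C_true <- X2 - X1
  stratum <- ifelse(C_true < 0, "improvement", "non_improvement")
  w_true <- numeric(n)
  for (s in c("improvement", "non_improvement")) {
    idx <- stratum == s
    if (any(idx)) {
      w_true[idx] <- sigmoid_weight(X1[idx], config$true_weight_params[[s]])
    }
  }
  cprime_true <- w_true * C_true
  latent <- -config$anchor_scale * cprime_true +
    stats::rnorm(n, 0, config$anchor_noise_sd)
  anchor <- 1L + rowSums(outer(latent, config$anchor_thresholds, ">="))
  likert <- c("strongly_disagree", "disagree", "neutral", "agree",
              "strongly_agree")[anchor]

  # covariates (calibrated to the reported cohort quantiles)
  age <- .clip01(stats::rnorm(n, 53, 10.5), 30, 85)
  menopause <- ifelse(stats::runif(n) < 0.51, "pre_peri", "post")
  et_months <- stats::rlnorm(n, log(9.9), 1.1)
  days_between <- round(.clip01(stats::rnorm(n, 54.5, 9), 42, 119))
  adherence <- .clip01(stats::rnorm(n, 50, 13), 0, days_between)
  vms_week <- stats::rgamma(n, shape = 1.55, scale = 29.1)

  lost <- stats::runif(n) < config$lost_to_followup_rate
  fdom[lost, ] <- NA_real_
  likert[stats::runif(n) < config$missing_anchor_rate] <- NA_character_

  cohort <- data.frame(
    couplet_id = sprintf("c%04d", seq_len(n)),
    patient_id = sprintf("p%04d", patient_idx),
    b_dom1 = bdom[, 1], b_dom2 = bdom[, 2], b_dom3 = bdom[, 3],
    f_dom1 = fdom[, 1], f_dom2 = fdom[, 2], f_dom3 = fdom[, 3],
    likert = likert,
    intervention = arm,
    age_years = age,
    menopause = menopause,
    et_months = et_months,
    adherence_days = adherence,
    days_between = days_between,
    vms_per_week = vms_week,
    stringsAsFactors = FALSE)
  out <- validate_cohort(cohort)
  attr(out, "provenance") <- sprintf("synthetic (seed %d)", config$seed)
  attr(out, "truth") <- data.frame(couplet_id = cohort$couplet_id,
                                   X1 = X1, C = C_true, w = w_true,
                                   C_prime = cprime_true, latent = latent)
  out
}

#' Generate a cohort with a known tree-structured response
#'
#' Builds predictor rows from the default covariate distributions and a
#' response equal to a region mean plus Gaussian noise, where regions
#' are defined by predictor levels. Used as an oracle for the nested
#' cross-validation machinery: with zero noise the fitted tree must
#' recover the partition, and with noise sd sigma the cross-validated
#' MSE has floor sigma^2.
#'
#' @param n Number of rows.
#' @param regions List of regions; each a list with `when` (named list:
#'   predictor name -> allowed levels) and `mean` (numeric). Regions
#'   must be mutually exclusive and jointly cover every generated row.
#' @param noise_sd SD of the response noise (default 0).
#' @param seed Integer seed.
#' @param missing_rate Fraction of missing values injected into each
#'   predictor other than intervention (default 0).
#' @return List with `x` (predictor data frame), `y` (response), and
#'   `region` (1-based region index per row).
#' @export
generate_known_tree_cohort <- function(n, regions, noise_sd = 0,
                                       seed = 1L, missing_rate = 0) {
  stopifnot(n >= 1, length(regions) >= 1, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  cfg <- generator_config(n_couplets = n, seed = seed,
                          lost_to_followup_rate = 0,
                          missing_anchor_rate = 0)
  cohort <- generate_cohort(cfg)
  x <- make_predictor_rows(cohort)

  # regions are resolved on the fully observed predictors; missingness
  # is injected afterwards so the true region stays defined for every row
  region <- integer(n)
  for (i in seq_len(n)) {
    hits <- which(vapply(regions, function(r) {
      all(vapply(names(r$when), function(v)
        as.character(x[[v]][i]) %in% r$when[[v]], logical(1)))
    }, logical(1)))
    if (length(hits) > 1L) {
      stop("overlapping regions: row ", i, " matches regions ",
           paste(hits, collapse = ", "), call. = FALSE)
    }
    if (length(hits) == 0L) {
      stop("regions do not cover row ", i, call. = FALSE)
    }
    region[i] <- hits
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed((seed + 1L) %% .Machine$integer.max)
  if (missing_rate > 0) {
    for (col in setdiff(names(x), "intervention")) {
      x[[col]][stats::runif(n) < missing_rate] <- NA
    }
  }
  means <- vapply(regions, `[[`, numeric(1), "mean")
  y <- means[region] + stats::rnorm(n, 0, noise_sd)
  list(x = x, y = y, region = region)
}
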