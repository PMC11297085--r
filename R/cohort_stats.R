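## Descriptive cohort summaries and Bonferroni-corrected comparisons ----

.med_iqr <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(data.frame(n = 0L, median = NA_real_, q1 = NA_real_,
                      q3 = NA_real_))
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
}

#' Descriptive cohort summary
#'
#' Median and interquartile range for the continuous baseline
#' characteristics (age, baseline HFRS composite, weekly VMS count,
#' endocrine-therapy months, adherence days, days between
#' questionnaires) and counts with percentages for the categorical ones
#' (intervention category, menopausal status, anchor response
#' availability). Percentages use the full couplet count as denominator.
#'
#' @param cohort A validated `vms_cohort`.
#' @return List with `n_couplets`, `n_patients`, `continuous` (data
#'   frame: variable, n, median, q1, q3) and `categorical` (data frame:
#'   variable, level, n, percent).
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  X1 <- .hfrs_vec(cohort$b_dom1, cohort$b_dom2, cohort$b_dom3)
  cont_vars <- list(age_years = cohort$age_years,
                    baseline_hfrs = X1,
                    vms_per_week = cohort$vms_per_week,
                    et_months = cohort$et_months,
                    adherence_days = cohort$adherence_days,
                    days_between = cohort$days_between)
  continuous <- do.call(rbind, lapply(names(cont_vars), function(v) {
    cbind(data.frame(variable = v, stringsAsFactors = FALSE),
          .med_iqr(cont_vars[[v]]))
  }))
  n <- nrow(cohort)
  cat_one <- function(name, v, levels) {
    v <- factor(v, levels = levels)
    tab <- table(v, useNA = "no")
    data.frame(variable = name, level = names(tab),
               n = as.integer(tab), percent = 100 * as.integer(tab) / n,
               stringsAsFactors = FALSE)
  }
  categorical <- rbind(
    cat_one("intervention", cohort$intervention, intervention_levels()),
    cat_one("menopause", cohort$menopause, menopause_levels()),
    cat_one("anchor_response",
            ifelse(is.na(cohort$likert), NA, "responded"), "responded"))
  list(n_couplets = n,
       n_patients = length(unique(cohort$patient_id)),
       continuous = continuous, categorical = categorical)
}

#' Two-group comparison with a Bonferroni significance flag
#'
#' Pooled-variance two-sample t test for continuous variables or a
#' Pearson chi-square test (no continuity correction) for categorical
#' ones, with the significance flag assessed at alpha = 0.05 divided by
#' the number of comparisons in the family.
#'
#' @param a,b For `kind = "continuous_t"`, numeric vectors (one per
#'   group). For `kind = "categorical_chi2"`, vectors of category labels
#'   (one per group).
#' @param kind Test family.
#' @param m_comparisons Number of comparisons in the Bonferroni family
#'   (default 1, i.e. no correction).
#' @return List with `statistic`, `df`, `p`, `alpha_corrected`,
#'   `significant_after_bonferroni`.
#' @export
compare_groups <- function(a, b,
                           kind = c("continuous_t", "categorical_chi2"),
                           m_comparisons = 1L) {
  kind <- match.arg(kind)
  stopifnot(m_comparisons >= 1)
  if (kind == "continuous_t") {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      stop("insufficient data: each group needs >= 2 values",
           call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    statistic <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) {
      stop("insufficient data: empty group", call. = FALSE)
    }
    lev <- sort(unique(c(as.character(a), as.character(b))))
    if (length(lev) < 2L) {
      stop("insufficient data: a single category", call. = FALSE)
    }
    tab <- rbind(table(factor(a, levels = lev)),
                 table(factor(b, levels = lev)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    statistic <- unname(ct$statistic)
    df <- unname(ct$parameter)
    p <- ct$p.value
  }
  alpha <- 0.05 / m_comparisons
  list(statistic = statistic, df = df, p = p,
       alpha_corrected = alpha,
       significant_after_bonferroni = is.finite(p) && p < alpha)
}
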