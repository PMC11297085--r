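# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ranks are computed by counting, correlations
# by explicit sums, and tree splits by exhaustive enumeration.

# mid-ranks by counting: rank_i = #smaller + (#equal + 1) / 2
oracle_midrank <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(a, b) {
  ra <- oracle_midrank(a)
  rb <- oracle_midrank(b)
  da <- ra - mean(ra)
  db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# exhaustive best binary split over all predictors: continuous splits at
# midpoints of sorted unique values, categorical splits over every proper
# bipartition of observed levels; returns the best SSE reduction and the
# row partition achieving it
oracle_best_split <- function(x, y, min_terminal = 2L) {
  sse <- function(v) sum((v - mean(v))^2)
  total <- sse(y)
  best <- list(reduction = -Inf, left = NULL)
  consider <- function(left) {
    if (sum(left) < min_terminal || sum(!left) < min_terminal) return()
    red <- total - sse(y[left]) - sse(y[!left])
    if (red > best$reduction + 1e-12) {
      best <<- list(reduction = red, left = left)
    }
  }
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (is.factor(v) || is.character(v)) {
      lev <- unique(as.character(v))
      k <- length(lev)
      if (k < 2L) next
      for (m in seq_len(2L^(k - 1L) - 1L)) {
        inset <- lev[bitwAnd(m, 2L^(seq_len(k) - 1L)) > 0L]
        consider(as.character(v) %in% inset)
      }
    } else {
      u <- sort(unique(v))
      if (length(u) < 2L) next
      for (t in (u[-length(u)] + u[-1]) / 2) consider(v < t)
    }
  }
  best
}

# SSE reduction achieved by an arbitrary row partition
partition_reduction <- function(y, left) {
  sse <- function(v) sum((v - mean(v))^2)
  sse(y) - sse(y[left]) - sse(y[!left])
}

# a random small CART instance: n rows, p predictors mixing continuous
# and categorical
random_split_instance <- function(seed, n = 10L, p = 3L) {
  set.seed(seed)
  x <- as.data.frame(lapply(seq_len(p), function(j) {
    if (j %% 2L == 1L) {
      round(stats::runif(n, 0, 10), 2)
    } else {
      factor(sample(letters[1:sample(2:4, 1)], n, replace = TRUE))
    }
  }))
  names(x) <- paste0("v", seq_len(p))
  list(x = x, y = round(stats::rnorm(n), 3))
}

# change records for one synthetic improvement-stratum calibration set:
# anchors generated from a KNOWN weight curve so recovery can be checked
make_stratum_records <- function(n, params, anchor_noise_sd = 0.5,
                                 seed = 1L,
                                 thresholds = c(-0.75, 0.25, 1.25, 2.5)) {
  set.seed(seed)
  X1 <- stats::runif(n, 0, 10)
  C <- -abs(stats::rnorm(n, 1.2, 1))
  w <- stats::plogis(params$b0 + params$b1 * X1)
  latent <- -w * C + stats::rnorm(n, 0, anchor_noise_sd)
  anchor <- 1L + rowSums(outer(latent, thresholds, ">="))
  data.frame(couplet_id = sprintf("s%04d", seq_len(n)),
             X1 = X1, X2 = X1 + C, C = C,
             stratum = factor("improvement",
                              levels = c("improvement", "non_improvement")),
             anchor = as.integer(anchor),
             stringsAsFactors = FALSE)
}

# minimal one-row cohort with every field present
one_row_cohort <- function() {
  data.frame(couplet_id = "c1", patient_id = "p1",
             b_dom1 = 4, b_dom2 = 5, b_dom3 = 6,
             f_dom1 = 2, f_dom2 = 3, f_dom3 = 4,
             likert = "agree", intervention = "cam",
             age_years = 52, menopause = "post", et_months = 10,
             adherence_days = 40, days_between = 50, vms_per_week = 30,
             stringsAsFactors = FALSE)
}

# a tiny BO budget for tests that only need a working optimizer
small_bo <- function(seed = 1L) {
  bo_config(n_init_points = 8L, n_repeats = 1L, n_iterations = 5L,
            seed = seed)
}
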