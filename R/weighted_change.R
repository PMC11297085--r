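## Sigmoid baseline weight, weighted change score, anchor calibration ----

#' Weight parameters for one change-direction stratum
#'
#' Holds the intercept and slope of the logistic baseline weight
#' w(X1) = 1 / (1 + exp(-(b0 + b1 * X1))), fitted separately for the
#' improvement (negative change) and non-improvement (zero or positive
#' change) strata.
#'
#' @param b0 Intercept (real, finite).
#' @param b1 Slope per HFRS unit (real, finite).
#' @param stratum `"improvement"` or `"non_improvement"`.
#' @return A `weight_params` list.
#' @export
weight_params <- function(b0, b1,
                          stratum = c("improvement", "non_improvement")) {
  stratum <- match.arg(stratum)
  if (!is.finite(b0) || !is.finite(b1)) {
    stop("weight parameters must be finite", call. = FALSE)
  }
  structure(list(b0 = b0, b1 = b1, stratum = stratum),
            class = "weight_params")
}

#' Logistic baseline weight
#'
#' Evaluates w = 1 / (1 + exp(-(b0 + b1 * X1))) at baseline composite
#' severity X1. The weight lies in (0, 1) (saturating to 1 within double
#' precision once b0 + b1 * X1 exceeds about 36) and is strictly
#' increasing in X1 when b1 > 0, so a given raw change counts for more at
#' higher baseline severity.
#'
#' @param X1 Baseline HFRS composite, in [0, 10]; vectorized.
#' @param params A [weight_params()] object.
#' @return Numeric vector of weights.
#' @examples
#' sigmoid_weight(6, weight_params(-10, 2.68))   # ~0.998, rounds to 1
#' @export
sigmoid_weight <- function(X1, params) {
  stopifnot(inherits(params, "weight_params"))
  if (any(!is.na(X1) & (X1 < 0 | X1 > 10))) {
    stop("X1 outside [0, 10]", call. = FALSE)
  }
  stats::plogis(params$b0 + params$b1 * X1)
}

#' Weighted change scores
#'
#' Applies the stratum-specific logistic baseline weight to each raw
#' change score: C' = w(X1) * C. Weighting preserves the direction of
#' change (sign(C') = sign(C)) and never inflates its magnitude
#' (|C'| <= |C|, strict while w < 1).
#'
#' @param records Change records as returned by [change_records()]
#'   (complete rows only).
#' @param params_by_stratum Named list with elements `improvement` and
#'   `non_improvement`, each a [weight_params()].
#' @return `records` with columns `w` and `C_prime` appended.
#' @export
weighted_change_score <- function(records, params_by_stratum) {
  needed <- levels(records$stratum)[levels(records$stratum) %in%
                                      unique(as.character(records$stratum))]
  missing_p <- setdiff(needed, names(params_by_stratum))
  if (length(missing_p) > 0L) {
    stop("no weight parameters supplied for stratum: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(records$C))) {
    stop("records must be complete (no missing change scores)",
         call. = FALSE)
  }
  w <- numeric(nrow(records))
  for (s in needed) {
    idx <- records$stratum == s
    w[idx] <- sigmoid_weight(records$X1[idx], params_by_stratum[[s]])
  }
  records$w <- w
  records$C_prime <- w * records$C
  records
}

#' Raw change needed to reach a target weighted change
#'
#' Inverts C' = w * C at a fixed weight: the raw HFRS reduction needed to
#' register a target weighted change is target / w, so patients with low
#' baseline severity (small w) need larger raw improvements to reach the
#' same weighted change.
#'
#' @param target_weighted Target weighted change magnitude.
#' @param w Weight in (0, 1].
#' @return `target_weighted / w`.
#' @examples
#' required_raw_change(2, 0.6)   # 3.33...: a 3.3-point raw reduction
#' @export
required_raw_change <- function(target_weighted, w) {
  if (any(w <= 0 | w > 1)) stop("w must lie in (0, 1]", call. = FALSE)
  target_weighted / w
}

#' Spearman rank correlation (mid-rank ties)
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#' Unlike `cor()`, a constant vector raises an error rather than
#' returning `NA`: an undefined correlation is never silently reported.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("vectors must have equal length >= 2", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(a, b, method = "spearman")
}

#' Default search box for the weight parameters
#'
#' b0 in [-10, 0], b1 in [0, 5]: an intercept range placing the weight
#' midpoint anywhere in the observable severity range and a nonnegative
#' slope so weight increases with baseline severity.
#'
#' @return A [search_box()] over `b0` and `b1`.
#' @export
weight_search_box <- function() {
  search_box(c("b0", "b1"), lower = c(-10, 0), upper = c(0, 5))
}

#' Fit the baseline weight by anchor calibration
#'
#' Estimates (b0, b1) for one change-direction stratum by Bayesian
#' optimization, choosing the weight curve whose weighted change score
#' C' = w(X1) * C correlates most strongly (Spearman) with the coded
#' treatment-effectiveness anchor. Only couplets with both a complete
#' change score and an anchor response enter the fit. By default the
#' objective is the absolute correlation |rho(C', anchor)|, so the same
#' criterion serves both strata regardless of the anchor's orientation;
#' `objective = "signed_max"` maximizes the signed correlation instead.
#'
#' @param records Change records ([change_records()]); rows of other
#'   strata or without anchors are dropped automatically.
#' @param stratum Which stratum to fit.
#' @param box Search box over (b0, b1); default [weight_search_box()].
#' @param opt A [bo_config()].
#' @param objective `"abs_max"` (default) or `"signed_max"`.
#' @param min_n Minimum calibration records required (default 5).
#' @return List with `params` (a [weight_params()]) and `report`: stratum,
#'   n, `rho_raw` (Spearman of C vs anchor), `rho_weighted` (Spearman of
#'   C' vs anchor at the optimum), b0, b1, and the optimizer trace.
#' @export
fit_weight_params <- function(records,
                              stratum = c("improvement", "non_improvement"),
                              box = weight_search_box(),
                              opt = bo_config(),
                              objective = c("abs_max", "signed_max"),
                              min_n = 5L) {
  stratum <- match.arg(stratum)
  objective <- match.arg(objective)
  sub <- records[!is.na(records$C) & !is.na(records$anchor) &
                   as.character(records$stratum) == stratum, , drop = FALSE]
  if (nrow(sub) < min_n) {
    stop(sprintf("insufficient data: %d anchor-complete record(s) in the %s stratum (need >= %d)",
                 nrow(sub), stratum, min_n), call. = FALSE)
  }
  if (length(unique(sub$anchor)) < 2L) {
    stop("correlation undefined: anchor is constant in this stratum",
         call. = FALSE)
  }
  score <- function(rho) if (objective == "abs_max") abs(rho) else rho
  obj <- function(x) {
    p <- weight_params(x[["b0"]], x[["b1"]], stratum)
    cp <- sigmoid_weight(sub$X1, p) * sub$C
    if (length(unique(cp)) < 2L) return(-1)   # degenerate curve: C' constant
    score(spearman_rho(cp, sub$anchor))
  }
  fit <- bo_maximize(obj, box, opt)
  params <- weight_params(fit$best_point[["b0"]], fit$best_point[["b1"]],
                          stratum)
  cp <- sigmoid_weight(sub$X1, params) * sub$C
  rho_raw <- if (length(unique(sub$C)) >= 2L)
    spearman_rho(sub$C, sub$anchor) else NA_real_
  rho_weighted <- if (length(unique(cp)) >= 2L)
    spearman_rho(cp, sub$anchor) else NA_real_
  list(params = params,
       report = list(stratum = stratum, n = nrow(sub),
                     b0 = params$b0, b1 = params$b1,
                     rho_raw = rho_raw, rho_weighted = rho_weighted,
                     objective = objective,
                     best_value = fit$best_value, trace = fit$trace))
}
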