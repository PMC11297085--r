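## HFRS composite scoring, Likert anchor coding, change records ----------

#' HFRS composite score
#'
#' The Hot Flush Rating Scale severity composite is the arithmetic mean of
#' three 0-10 domain scores (distress, problems, disruption to daily life).
#' The composite is defined only for complete responses: a couplet missing
#' any of the three domains gets `complete = FALSE` and no value. Partial
#' means are never substituted.
#'
#' @param domains Numeric vector of length 3; `NA` marks a missing domain.
#' @return A list with `value` (mean of the three domains, or `NA` when
#'   incomplete) and `complete` (logical).
#' @examples
#' hfrs_score(c(4, 5, 6))      # value 5, complete
#' hfrs_score(c(4, NA, 6))     # incomplete, value NA
#' @export
hfrs_score <- function(domains) {
  if (length(domains) != 3L || !is.numeric(domains)) {
    stop("domains must be a numeric vector of length 3", call. = FALSE)
  }
  present <- !is.na(domains)
  if (any(domains[present] < 0 | domains[present] > 10)) {
    stop("domain score outside [0, 10]", call. = FALSE)
  }
  if (all(present)) {
    list(value = mean(domains), complete = TRUE)
  } else {
    list(value = NA_real_, complete = FALSE)
  }
}

.hfrs_vec <- function(d1, d2, d3) {
  m <- cbind(d1, d2, d3)
  value <- rowMeans(m)           # NA whenever any domain missing
  value
}

#' Code the treatment-effectiveness Likert anchor
#'
#' Maps the five-level agreement response ("my treatment adequately
#' controls my VMS") to an integer score: strongly_disagree = 1 up to
#' strongly_agree = 5. "Not applicable" responses are coded as neutral
#' (3); missing stays missing.
#'
#' @param raw Character vector of Likert labels (see [cohort_columns()]
#'   schema), or `NA`.
#' @return Integer vector of anchor scores in 1-5, `NA` where missing.
#' @examples
#' code_likert(c("strongly_agree", "not_applicable", NA))
#' @export
code_likert <- function(raw) {
  map <- c(strongly_disagree = 1L, disagree = 2L, neutral = 3L,
           agree = 4L, strongly_agree = 5L, not_applicable = 3L)
  raw <- as.character(raw)
  known <- is.na(raw) | raw %in% names(map)
  if (!all(known)) {
    stop("unrecognised Likert label: '", raw[which(!known)[1L]], "'",
         call. = FALSE)
  }
  out <- unname(map[raw])
  out[is.na(raw)] <- NA_integer_
  out
}

#' Change records for a cohort
#'
#' Computes, per couplet, the baseline composite `X1`, follow-up composite
#' `X2`, raw change `C = X2 - X1`, the change-direction stratum, and the
#' coded effectiveness anchor. A couplet contributes a change record only
#' when both composites are complete (all six domains answered); other
#' couplets are excluded, never imputed. Improvement is a strictly
#' negative change; zero or positive change is non-improvement.
#'
#' @param cohort A validated `vms_cohort` data frame.
#' @param complete_only Drop couplets without both composites
#'   (default `TRUE`). With `FALSE` the excluded rows are retained with
#'   `NA` change fields, for bookkeeping.
#' @return Data frame with columns `couplet_id`, `X1`, `X2`, `C`,
#'   `stratum` (factor: improvement / non_improvement) and `anchor`
#'   (integer 1-5 or `NA`).
#' @export
change_records <- function(cohort, complete_only = TRUE) {
  cohort <- validate_cohort(cohort)
  X1 <- .hfrs_vec(cohort$b_dom1, cohort$b_dom2, cohort$b_dom3)
  X2 <- .hfrs_vec(cohort$f_dom1, cohort$f_dom2, cohort$f_dom3)
  C <- X2 - X1
  stratum <- factor(ifelse(C < 0, "improvement", "non_improvement"),
                    levels = c("improvement", "non_improvement"))
  rec <- data.frame(couplet_id = cohort$couplet_id,
                    X1 = X1, X2 = X2, C = C,
                    stratum = stratum,
                    anchor = code_likert(cohort$likert),
                    stringsAsFactors = FALSE)
  if (complete_only) rec <- rec[!is.na(rec$C), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
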