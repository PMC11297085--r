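#' @keywords internal
"_PACKAGE"

## Canonical cohort schema -----------------------------------------------

#' Canonical cohort column names
#'
#' The fixed header of the cohort CSV. One row per survey couplet (a paired
#' baseline and six-week follow-up questionnaire). Patients may contribute
#' more than one couplet; `patient_id` is retained for descriptive counts
#' only and every couplet is analysed as an independent row.
#'
#' @return Character vector of the sixteen canonical column names, in order.
#' @export
cohort_columns <- function() {
  c("couplet_id", "patient_id",
    "b_dom1", "b_dom2", "b_dom3",
    "f_dom1", "f_dom2", "f_dom3",
    "likert", "intervention",
    "age_years", "menopause", "et_months",
    "adherence_days", "days_between", "vms_per_week")
}

#' Recognised factor levels for categorical cohort fields
#' @name cohort_levels
#' @keywords internal
NULL

likert_levels <- function() {
  c("strongly_disagree", "disagree", "neutral", "agree", "strongly_agree",
    "not_applicable")
}

intervention_levels <- function() {
  c("lifestyle", "cam", "drug", "endocrine_modification", "control")
}

menopause_levels <- function() {
  c("pre_peri", "post")
}

.domain_cols <- function() c("b_dom1", "b_dom2", "b_dom3",
                             "f_dom1", "f_dom2", "f_dom3")
.numeric_cols <- function() c(.domain_cols(), "age_years", "et_months",
                              "adherence_days", "days_between",
                              "vms_per_week")

## Validation -------------------------------------------------------------

#' Validate a cohort table
#'
#' Checks every structural invariant of the canonical schema: all sixteen
#' columns present, unique couplet identifiers, every present domain score
#' in [0, 10], nonnegative continuous covariates, `days_between >= 1`, and
#' categorical fields drawn from their recognised level sets. Violations
#' raise an error naming the offending row and field; rows are never
#' silently dropped or clamped.
#'
#' @param cohort A data frame in the canonical cohort layout.
#' @return The validated cohort, invisibly, with class `vms_cohort`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("malformed cohort: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[, cohort_columns(), drop = FALSE]

  .bad_row <- function(ok, field, why) {
    bad <- which(!ok)
    if (length(bad) > 0L) {
      stop(sprintf("invalid cohort: row %d, field '%s': %s",
                   bad[1L], field, why), call. = FALSE)
    }
  }

  ids <- as.character(cohort$couplet_id)
  if (anyDuplicated(ids)) {
    stop("invalid cohort: duplicated couplet_id '",
         ids[anyDuplicated(ids)], "'", call. = FALSE)
  }
  .bad_row(!is.na(ids) & nzchar(ids), "couplet_id", "must be non-empty")

  for (col in .domain_cols()) {
    v <- cohort[[col]]
    if (!is.numeric(v)) stop("field '", col, "' must be numeric", call. = FALSE)
    .bad_row(is.na(v) | (v >= 0 & v <= 10), col,
             "domain score outside [0, 10]")
  }
  for (col in c("age_years", "et_months", "adherence_days", "vms_per_week")) {
    v <- cohort[[col]]
    if (!is.numeric(v)) stop("field '", col, "' must be numeric", call. = FALSE)
    .bad_row(is.na(v) | v >= 0, col, "must be nonnegative")
  }
  db <- cohort$days_between
  .bad_row(is.na(db) | (db >= 1 & db == round(db)), "days_between",
           "must be a positive integer")

  .check_levels <- function(col, levels, allow_missing = TRUE) {
    v <- as.character(cohort[[col]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    ok <- v %in% levels
    if (allow_missing) ok <- ok | is.na(v)
    .bad_row(ok, col, paste0("unrecognised label (expected one of: ",
                             paste(levels, collapse = ", "), ")"))
    cohort[[col]] <<- v
  }
  .check_levels("likert", likert_levels())
  .check_levels("intervention", intervention_levels(), allow_missing = FALSE)
  .check_levels("menopause", menopause_levels())

  cohort$couplet_id <- ids
  cohort$patient_id <- as.character(cohort$patient_id)
  class(cohort) <- unique(c("vms_cohort", class(cohort)))
  invisible(cohort)
}

## IO ---------------------------------------------------------------------

#' Read a cohort table from delimited text
#'
#' Reads the canonical cohort CSV (UTF-8, fixed header, empty cells for
#' missing values) and validates it. Out-of-range domain scores and
#' unknown categorical labels are rejected with an error naming the row
#' and field; nothing is clamped or imputed at read time.
#'
#' @param path Path to a delimited text file with the canonical header.
#' @param sep Field delimiter (default comma).
#' @return A validated `vms_cohort` data frame with a `provenance`
#'   attribute recording the source path.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           na.strings = "", quote = "\"",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .numeric_cols()) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("invalid cohort: row %d, field '%s': not numeric ('%s')",
                   bad[1L], col, v[bad[1L]]), call. = FALSE)
    }
    raw[[col]] <- num
  }
  cohort <- validate_cohort(raw)
  attr(cohort, "provenance") <- path
  cohort
}

#' Write a cohort table as delimited text
#'
#' Writes the canonical CSV layout: fixed header order, empty cells for
#' missing values, no quoting, no row names. A written cohort re-read with
#' [read_cohort()] reproduces the original field-by-field (numeric fields
#' to full double precision).
#'
#' @param cohort A validated `vms_cohort` (or coercible data frame).
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  cohort <- validate_cohort(cohort)
  out <- as.data.frame(cohort)[, cohort_columns(), drop = FALSE]
  for (col in .numeric_cols()) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
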