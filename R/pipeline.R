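## One-command orchestration: cohort -> scores -> weights -> tree -------

#' Pipeline run configuration
#'
#' Exactly one of `input` (path to a cohort CSV) or `generator` (a
#' [generator_config()]) selects the cohort source.
#'
#' @param out_dir Output directory (created if absent).
#' @param input Optional path to a cohort CSV.
#' @param generator Optional [generator_config()].
#' @param seed Master seed for weight fitting, tree tuning and leaf
#'   bootstraps.
#' @param weight_box,hp_box Search boxes for the weight parameters and
#'   tree hyperparameters.
#' @param weight_opt,cv_opt [bo_config()]s for the two optimizations.
#' @param objective Objective convention for [fit_weight_params()].
#' @param k_outer,k_inner Nested-CV fold counts.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, input = NULL, generator = NULL,
                       seed = 20210903L,
                       weight_box = weight_search_box(),
                       hp_box = hp_search_box(),
                       weight_opt = bo_config(seed = seed),
                       cv_opt = bo_config(n_init_points = 10L,
                                          n_repeats = 2L,
                                          n_iterations = 10L,
                                          seed = seed),
                       objective = "abs_max",
                       k_outer = 10L, k_inner = 5L) {
  if (is.null(input) == is.null(generator)) {
    stop("supply exactly one of 'input' or 'generator'", call. = FALSE)
  }
  structure(list(out_dir = out_dir, input = input, generator = generator,
                 seed = as.integer(seed), weight_box = weight_box,
                 hp_box = hp_box, weight_opt = weight_opt,
                 cv_opt = cv_opt, objective = objective,
                 k_outer = as.integer(k_outer),
                 k_inner = as.integer(k_inner)),
            class = "run_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  path
}

#' Run the full weighted-change analysis pipeline
#'
#' Generates or ingests a cohort, then runs every stage in order:
#' descriptive summary, change records, anchor-calibrated weight fitting
#' per change-direction stratum (on the anchor-complete subset), weighted
#' change scores for all complete couplets, collinearity screening of the
#' tree predictors, and the nested-CV regression tree. Each stage's
#' output is serialized into `out_dir` (all files re-readable by the
#' package's own readers) together with a manifest of seeds, versions
#' and output checksums; a rerun with the same configuration reproduces
#' every file bit for bit.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  stage <- "ingest"
  res <- tryCatch({
    cohort <- if (!is.null(config$input)) {
      read_cohort(config$input)
    } else {
      generate_cohort(config$generator)
    }
    if (nrow(cohort) == 0L) {
      stop("empty cohort: nothing to score", call. = FALSE)
    }
    write_cohort(cohort, p("cohort.csv"))

    stage <- "summary"
    summary <- summarize_cohort(cohort)
    utils::write.csv(summary$continuous, p("summary_continuous.csv"),
                     row.names = FALSE)
    utils::write.csv(summary$categorical, p("summary_categorical.csv"),
                     row.names = FALSE)

    stage <- "scoring"
    records <- change_records(cohort)
    if (nrow(records) == 0L) {
      stop("no couplet has complete baseline and follow-up composites",
           call. = FALSE)
    }
    utils::write.csv(records, p("change_records.csv"), row.names = FALSE)

    stage <- "weight fitting"
    fits <- lapply(c("improvement", "non_improvement"), function(s) {
      fit_weight_params(records, stratum = s, box = config$weight_box,
                        opt = config$weight_opt,
                        objective = config$objective)
    })
    names(fits) <- c("improvement", "non_improvement")
    .write_json(lapply(fits, function(f)
      f$report[c("stratum", "n", "b0", "b1", "rho_raw", "rho_weighted",
                 "objective")]),
      p("weight_fits.json"))
    params <- lapply(fits, `[[`, "params")

    stage <- "weighted change"
    weighted <- weighted_change_score(records, params)
    utils::write.csv(weighted, p("weighted_change.csv"),
                     row.names = FALSE)

    stage <- "predictors"
    keep <- cohort$couplet_id %in% weighted$couplet_id
    x <- make_predictor_rows(cohort[keep, , drop = FALSE])
    vif <- vif_check(x)
    utils::write.csv(vif, p("vif.csv"), row.names = FALSE)

    stage <- "nested cross-validation"
    y <- weighted$C_prime[match(rownames(x), weighted$couplet_id)]
    cv <- run_nested_cv(x, y, box = config$hp_box, opt = config$cv_opt,
                        seed = config$seed, k_outer = config$k_outer,
                        k_inner = config$k_inner)
    .write_json(list(outer_fold_mses = cv$outer_fold_mses,
                     mean_mse = cv$mean_mse,
                     mse_interval = cv$mse_interval,
                     chosen_hp = lapply(cv$chosen_hp, unclass),
                     final_hp = unclass(cv$final_hp)),
                p("cv_report.json"))
    .write_json(tree_to_list(cv$final_model, seed = config$seed),
                p("tree.json"))
    writeLines(tree_text(cv$final_model, seed = config$seed),
               p("tree.txt"))

    list(cohort = cohort, summary = summary, records = records,
         fits = fits, weighted = weighted, vif = vif, cv = cv)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s",
                 stage, conditionMessage(e)), call. = FALSE)
  })

  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package = "vmswc",
    version = as.character(utils::packageVersion("vmswc")),
    seed = config$seed,
    source = if (!is.null(config$input)) config$input else
      sprintf("generator(seed=%d, n=%d)", config$generator$seed,
              config$generator$n_couplets),
    k_outer = config$k_outer, k_inner = config$k_inner,
    objective = config$objective,
    files = lapply(stats::setNames(outputs, outputs), function(f)
      unname(tools::md5sum(file.path(config$out_dir, f)))))
  .write_json(manifest, p("manifest.json"))
  invisible(c(res, list(out_dir = config$out_dir, manifest = manifest)))
}
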