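## Ten-fold nested cross-validation with inner five-fold CV and
## Bayesian hyperparameter tuning.

.make_folds <- function(n, k) {
  # seeded caller; balanced random assignment
  sample(rep_len(seq_len(k), n))
}

.cv_mse <- function(x, y, folds, hp, use_surrogates = TRUE) {
  errs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    tree <- grow_tree(x[tr, , drop = FALSE], y[tr], hp,
                      use_surrogates = use_surrogates)
    pred <- predict(tree, x[!tr, , drop = FALSE])
    mean((y[!tr] - pred)^2)
  }, numeric(1))
  mean(errs)
}

.hp_from_point <- function(p) {
  tree_hyperparams(min_parent = p[["min_parent"]],
                   min_terminal = min(p[["min_terminal"]],
                                      p[["min_parent"]]),
                   cp = p[["cp"]],
                   max_depth = p[["max_depth"]])
}

#' Nested cross-validation for the weighted-change regression tree
#'
#' Outer ten-fold cross-validation estimates generalization error while
#' an inner loop tunes the tree hyperparameters: within each outer
#' training set, five-fold cross-validated MSE is minimized over the
#' hyperparameter box by GP-UCB Bayesian optimization ([bo_maximize()]
#' on the negated MSE). The tuned tree is refit on the outer training
#' set and scored on the held-out fold, so no test row ever informs its
#' own hyperparameters. The final reported model is refit on all rows
#' with the modal per-fold hyperparameters (ties broken by the lowest
#' cp). The MSE interval is mean +/- 1.96 * sd / sqrt(k_outer).
#'
#' @param x Predictor data frame ([make_predictor_rows()]).
#' @param y Numeric response (weighted change scores), complete.
#' @param box Hyperparameter [search_box()]; default [hp_search_box()].
#' @param opt A [bo_config()] for the inner tuning. When a candidate
#'   point has `min_terminal > min_parent` the terminal bound is clamped
#'   to the parent bound at evaluation time.
#' @param seed Integer seed governing fold assignment and tuning.
#' @param k_outer,k_inner Fold counts (defaults 10 and 5).
#' @return A `nested_cv` list: `outer_fold_mses`, `mean_mse`,
#'   `mse_interval`, `chosen_hp` (per-fold [tree_hyperparams()]),
#'   `final_hp`, `final_model`, `seed`.
#' @export
run_nested_cv <- function(x, y, box = hp_search_box(),
                          opt = bo_config(), seed = 1L,
                          k_outer = 10L, k_inner = 5L) {
  n <- length(y)
  stopifnot(is.data.frame(x), nrow(x) == n)
  if (n < 30L) stop("need at least 30 rows for nested CV", call. = FALSE)
  if (n / k_outer < 3 || (n * (k_outer - 1) / k_outer) / k_inner < 2) {
    stop("folds too small for this sample; use fewer folds", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)

  set.seed(seed %% .Machine$integer.max)
  outer_folds <- .make_folds(n, k_outer)
  inner_seeds <- sample.int(.Machine$integer.max - 1L, k_outer)

  outer_mses <- numeric(k_outer)
  chosen_hp <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    tr <- outer_folds != f
    xt <- x[tr, , drop = FALSE]
    yt <- y[tr]
    set.seed(inner_seeds[f])
    inner_folds <- .make_folds(length(yt), k_inner)   # fixed per outer fold
    objective <- function(p) {
      hp <- .hp_from_point(p)
      -.cv_mse(xt, yt, inner_folds, hp)
    }
    fit <- bo_maximize(objective, box,
                       bo_config(n_init_points = opt$n_init_points,
                                 n_repeats = opt$n_repeats,
                                 n_iterations = opt$n_iterations,
                                 kappa = opt$kappa,
                                 seed = inner_seeds[f]))
    hp <- .hp_from_point(fit$best_point)
    chosen_hp[[f]] <- hp
    tree <- grow_tree(xt, yt, hp)
    pred <- predict(tree, x[!tr, , drop = FALSE])
    outer_mses[f] <- mean((y[!tr] - pred)^2)
  }

  # modal hyperparameters across folds; ties -> lowest cp
  keys <- vapply(chosen_hp, function(h)
    paste(h$min_parent, h$min_terminal, h$cp, h$max_depth, sep = "|"),
    character(1))
  tab <- table(keys)
  modal <- names(tab)[tab == max(tab)]
  cps <- vapply(modal, function(k)
    chosen_hp[[match(k, keys)]]$cp, numeric(1))
  final_hp <- chosen_hp[[match(modal[which.min(cps)], keys)]]
  final_model <- grow_tree(x, y, final_hp)

  mean_mse <- mean(outer_mses)
  half <- 1.96 * stats::sd(outer_mses) / sqrt(k_outer)
  structure(list(outer_fold_mses = outer_mses,
                 mean_mse = mean_mse,
                 mse_interval = c(mean_mse - half, mean_mse + half),
                 chosen_hp = chosen_hp,
                 final_hp = final_hp,
                 final_model = final_model,
                 outer_folds = outer_folds,
                 seed = seed),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("Nested CV (%d outer folds): mean MSE %.4f (95%% CI %.4f, %.4f)\n",
              length(x$outer_fold_mses), x$mean_mse,
              x$mse_interval[1], x$mse_interval[2]))
  cat(sprintf("Final hyperparameters: min_parent=%d min_terminal=%d cp=%.4g max_depth=%d\n",
              x$final_hp$min_parent, x$final_hp$min_terminal,
              x$final_hp$cp, x$final_hp$max_depth))
  invisible(x)
}
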