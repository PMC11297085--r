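## Regression-tree engine: rpart-backed fitting, surrogate splits,
## node-level reporting, predictor derivation, and collinearity checks.

#' Regression-tree hyperparameters
#'
#' The four tuned hyperparameters of the regression tree. `cp` follows
#' the rpart convention: a split is kept only when it reduces the overall
#' relative error (deviance scaled by the root deviance) by at least
#' `cp`. `max_depth` counts the root as level 1.
#'
#' @param min_parent Minimum observations a node needs to be split.
#' @param min_terminal Minimum observations in any terminal node; must
#'   not exceed `min_parent`.
#' @param cp Complexity parameter, > 0.
#' @param max_depth Maximum tree depth (root = level 1).
#' @return A `tree_hyperparams` list.
#' @export
tree_hyperparams <- function(min_parent = 20L, min_terminal = 7L,
                             cp = 0.01, max_depth = 5L) {
  min_parent <- as.integer(round(min_parent))
  min_terminal <- as.integer(round(min_terminal))
  max_depth <- as.integer(round(max_depth))
  stopifnot(min_parent >= 2, min_terminal >= 1,
            min_terminal <= min_parent, cp > 0, max_depth >= 1)
  structure(list(min_parent = min_parent, min_terminal = min_terminal,
                 cp = cp, max_depth = max_depth),
            class = "tree_hyperparams")
}

#' Hyperparameter search box for tree tuning
#'
#' The bounds searched during nested cross-validation: minimum parent
#' node size 5-20, minimum terminal node size 2-10, complexity parameter
#' 0.001-0.1, and maximum depth 3-7 levels.
#'
#' @return A [search_box()] over the four hyperparameters.
#' @export
hp_search_box <- function() {
  search_box(c("min_parent", "min_terminal", "cp", "max_depth"),
             lower = c(5, 2, 0.001, 3),
             upper = c(20, 10, 0.1, 7),
             kind = c("integer", "integer", "real", "integer"))
}

#' Derive the modelling predictors from a cohort
#'
#' Builds the six-predictor design used in the regression-tree analysis:
#' time between questionnaires dichotomized at 56 days (the six-week
#' follow-up plus the two-week reminder window), intervention category
#' (5 levels, never missing), age in three bands (default < 50, 50-59,
#' >= 60 years), patient-reported adherence in days (continuous),
#' menopausal status at diagnosis (2 levels), and duration of endocrine
#' therapy dichotomized at 12 months (VMS are typically most severe in
#' the first year of therapy).
#'
#' @param cohort A validated `vms_cohort`.
#' @param age_breaks Two interior cut points for the age bands.
#' @param days_cut Dichotomization point for days between questionnaires.
#' @param et_cut Dichotomization point (months) for endocrine-therapy
#'   duration.
#' @return Data frame of predictors, one row per couplet, with
#'   `couplet_id` row names; missing covariates stay `NA` (the tree
#'   routes them by surrogate splits).
#' @export
make_predictor_rows <- function(cohort, age_breaks = c(50, 60),
                                days_cut = 56, et_cut = 12) {
  cohort <- validate_cohort(cohort)
  stopifnot(length(age_breaks) == 2L, age_breaks[1] < age_breaks[2])
  age_level <- cut(cohort$age_years,
                   breaks = c(-Inf, age_breaks, Inf),
                   labels = c(paste0("<", age_breaks[1]),
                              paste0(age_breaks[1], "-", age_breaks[2] - 1),
                              paste0(">=", age_breaks[2])),
                   right = FALSE)
  out <- data.frame(
    days_between_level = factor(
      ifelse(is.na(cohort$days_between), NA,
             ifelse(cohort$days_between <= days_cut,
                    paste0("<=", days_cut), paste0(">", days_cut))),
      levels = c(paste0("<=", days_cut), paste0(">", days_cut))),
    intervention = factor(cohort$intervention,
                          levels = intervention_levels()),
    age_level = age_level,
    adherence_days = cohort$adherence_days,
    menopause = factor(cohort$menopause, levels = menopause_levels()),
    et_duration_level = factor(
      ifelse(is.na(cohort$et_months), NA,
             ifelse(cohort$et_months < et_cut,
                    paste0("<", et_cut), paste0(">=", et_cut))),
      levels = c(paste0("<", et_cut), paste0(">=", et_cut))),
    row.names = cohort$couplet_id,
    stringsAsFactors = FALSE)
  if (anyNA(out$intervention)) {
    stop("intervention must never be missing", call. = FALSE)
  }
  out
}

#' Grow a regression tree on weighted change scores
#'
#' Recursive binary partitioning minimizing within-node sums of squares
#' (CART, anova method), with exhaustive binary partition search over
#' categorical levels, rpart-convention cp pruning, and surrogate splits
#' so rows missing a split variable are routed by the best agreeing
#' backup rule (majority direction when no surrogate helps). A constant
#' response or fewer than `min_parent` rows yields a single-node tree.
#'
#' @param x Predictor data frame (see [make_predictor_rows()]).
#' @param y Numeric response (the weighted change scores), no missing
#'   values, same length as `nrow(x)`.
#' @param hp A [tree_hyperparams()].
#' @param use_surrogates Route missing values by surrogate splits
#'   (default `TRUE`); `FALSE` drops them down the majority branch only.
#' @return A `vms_tree`: the rpart fit plus retained training responses
#'   and leaf membership.
#' @export
grow_tree <- function(x, y, hp = tree_hyperparams(),
                      use_surrogates = TRUE) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  if (anyNA(y) || !all(is.finite(y))) {
    stop("response must be finite with no missing values", call. = FALSE)
  }
  dat <- cbind(.y = y, x)
  # rpart counts the root as depth 0 where this package counts it as
  # level 1; a max_depth of 1 forbids any split at all.
  ctrl <- rpart::rpart.control(
    minsplit = hp$min_parent, minbucket = hp$min_terminal,
    cp = if (hp$max_depth == 1L) 2 else hp$cp,
    maxdepth = max(hp$max_depth - 1L, 1L),
    xval = 0L, maxcompete = 0L,
    maxsurrogate = if (use_surrogates) 5L else 0L,
    usesurrogate = if (use_surrogates) 2L else 0L,
    surrogatestyle = 0L)
  fit <- rpart::rpart(.y ~ ., data = dat, method = "anova", control = ctrl)
  structure(list(fit = fit, hp = hp, y = y,
                 where = fit$where,
                 node_of_row = as.integer(rownames(fit$frame))[fit$where]),
            class = "vms_tree")
}

#' @export
print.vms_tree <- function(x, ...) {
  cat(tree_text(x), sep = "\n")
  invisible(x)
}

#' Predict from a fitted tree
#'
#' Routes each row through the primary splits, falling back to surrogate
#' rules and then the majority direction when the split variable is
#' missing, and returns the training mean of the terminal node reached.
#'
#' @param object A `vms_tree`.
#' @param newdata Predictor data frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of leaf-mean predictions.
#' @export
predict.vms_tree <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newdata = newdata,
                            type = "vector"))
}

## --- node structure extraction -----------------------------------------

# Members (training-row indices) of an arbitrary node number: rows whose
# terminal node descends from it (node m descends from n iff n is a
# prefix of m in the binary node numbering).
.node_members <- function(tree, node) {
  leaf_nodes <- tree$node_of_row
  is_desc <- vapply(leaf_nodes, function(m) {
    while (m >= node) {
      if (m == node) return(TRUE)
      m <- m %/% 2L
    }
    FALSE
  }, logical(1))
  which(is_desc)
}

# Human-readable left-branch ("yes") condition for split row `k` of an
# rpart splits matrix.
.split_label <- function(fit, k) {
  sp <- fit$splits[k, , drop = FALSE]
  var <- rownames(fit$splits)[k]
  ncat <- sp[, "ncat"]
  if (ncat < 2) {    # continuous: ncat -1 => left if x < index, +1 => >=
    op <- if (ncat == -1) "<" else ">="
    sprintf("%s %s %.4g", var, op, sp[, "index"])
  } else {
    csp <- fit$csplit[sp[, "index"], seq_len(ncat)]
    lev <- attr(fit, "xlevels")[[var]]
    sprintf("%s in {%s}", var, paste(lev[csp == 1L], collapse = ", "))
  }
}

# Rows of fit$splits belonging to each internal node, in frame order.
# With maxcompete = 0 the layout per internal node is: primary split,
# then frame$nsurrogate surrogate rows.
.split_rows_by_node <- function(fit) {
  frame <- fit$frame
  out <- list()
  row <- 1L
  for (i in seq_len(nrow(frame))) {
    if (frame$var[i] == "<leaf>") next
    nsur <- frame$nsurrogate[i]
    out[[rownames(frame)[i]]] <- list(primary = row,
                                      surrogates = if (nsur > 0)
                                        seq(row + 1L, row + nsur) else integer(0))
    row <- row + 1L + nsur
  }
  out
}

#' Nested node-list representation of a fitted tree
#'
#' Walks the tree into a nested list: per node the split variable and
#' left-branch ("yes") rule, ordered surrogate rules with their agreement,
#' member count, mean and median response, and for terminal nodes the
#' bootstrap interval for the median from [node_summary()].
#'
#' @param tree A `vms_tree`.
#' @param boot_reps,seed Passed to [node_summary()] for leaf intervals.
#' @return Nested list (suitable for JSON serialization).
#' @export
tree_to_list <- function(tree, boot_reps = 2000L, seed = 1L) {
  fit <- tree$fit
  frame <- fit$frame
  splits_by_node <- .split_rows_by_node(fit)
  leaf_sum <- node_summary(tree, boot_reps = boot_reps, seed = seed)

  build <- function(node) {
    i <- match(as.character(node), rownames(frame))
    members <- .node_members(tree, node)
    yv <- tree$y[members]
    out <- list(node = node,
                n = frame$n[i],
                mean = mean(yv),
                median = stats::median(yv))
    if (frame$var[i] == "<leaf>") {
      ls <- leaf_sum[leaf_sum$node == node, ]
      out$interval <- c(ls$interval_low, ls$interval_high)
      out$leaf <- TRUE
    } else {
      sr <- splits_by_node[[as.character(node)]]
      out$split <- .split_label(fit, sr$primary)
      out$split_var <- rownames(fit$splits)[sr$primary]
      out$surrogates <- lapply(sr$surrogates, function(k) {
        list(rule = .split_label(fit, k),
             agreement = unname(fit$splits[k, "improve"]))
      })
      out$leaf <- FALSE
      out$yes <- build(2L * node)
      out$no <- build(2L * node + 1L)
    }
    out
  }
  build(1L)
}

#' Terminal-node summaries
#'
#' Per terminal node: member count, median weighted change, and a 95%
#' bootstrap percentile interval for the median (2000 resamples, seeded).
#' A leaf with fewer than two members reports the degenerate interval
#' [median, median].
#'
#' @param tree A `vms_tree`.
#' @param boot_reps Bootstrap resamples (default 2000).
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return Data frame: node, n, median, interval_low, interval_high.
#' @export
node_summary <- function(tree, boot_reps = 2000L, level = 0.95,
                         seed = 1L) {
  frame <- tree$fit$frame
  leaves <- as.integer(rownames(frame))[frame$var == "<leaf>"]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  alpha <- (1 - level) / 2
  rows <- lapply(leaves, function(node) {
    yv <- tree$y[tree$node_of_row == node]
    med <- stats::median(yv)
    if (length(yv) < 2L || length(unique(yv)) == 1L) {
      lo <- hi <- med
    } else {
      boots <- replicate(boot_reps,
                         stats::median(sample(yv, replace = TRUE)))
      qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                            type = 7)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(node = node, n = length(yv), median = med,
               interval_low = lo, interval_high = hi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Indented text diagram of a fitted tree
#'
#' Renders the tree with the left branch answering "yes" to the split
#' question; terminal nodes show the median and its 95% bootstrap
#' interval.
#'
#' @param tree A `vms_tree`.
#' @param ... Passed to [tree_to_list()].
#' @return Character vector of diagram lines.
#' @export
tree_text <- function(tree, ...) {
  nodes <- tree_to_list(tree, ...)
  lines <- character(0)
  walk <- function(nd, depth, label) {
    pad <- strrep("  ", depth)
    if (isTRUE(nd$leaf)) {
      lines <<- c(lines, sprintf(
        "%s%s[leaf n=%d] median %.2f (95%% CI %.2f, %.2f)",
        pad, label, nd$n, nd$median, nd$interval[1], nd$interval[2]))
    } else {
      lines <<- c(lines, sprintf("%s%s[%s? n=%d] mean %.2f",
                                 pad, label, nd$split, nd$n, nd$mean))
      walk(nd$yes, depth + 1L, "yes: ")
      walk(nd$no, depth + 1L, "no:  ")
    }
  }
  walk(nodes, 0L, "")
  lines
}

#' Structural validation of a fitted tree
#'
#' Walks the tree and checks every invariant the hyperparameters promise:
#' internal nodes have at least `min_parent` members, terminal nodes at
#' least `min_terminal`, depth never exceeds `max_depth` (root = 1), and
#' each pair of children partitions its parent.
#'
#' @param tree A `vms_tree`.
#' @return `TRUE` invisibly; violations raise an error.
#' @export
validate_tree <- function(tree) {
  frame <- tree$fit$frame
  hp <- tree$hp
  nodes <- as.integer(rownames(frame))
  for (i in seq_along(nodes)) {
    node <- nodes[i]
    depth <- floor(log2(node)) + 1L
    if (depth > hp$max_depth) stop("node ", node, " exceeds max_depth")
    if (frame$var[i] == "<leaf>") {
      if (frame$n[i] < hp$min_terminal && node != 1L) {
        stop("leaf ", node, " smaller than min_terminal")
      }
    } else {
      if (frame$n[i] < hp$min_parent) {
        stop("internal node ", node, " smaller than min_parent")
      }
      kids <- match(as.character(c(2L * node, 2L * node + 1L)),
                    rownames(frame))
      if (anyNA(kids)) stop("internal node ", node, " missing a child")
      if (sum(frame$n[kids]) != frame$n[i]) {
        stop("children of node ", node, " do not partition it")
      }
    }
  }
  invisible(TRUE)
}

## --- collinearity screening --------------------------------------------

#' Variance inflation factors of the predictor design
#'
#' Dummy-encodes the predictors (complete cases), regresses each encoded
#' column on all the others, and reports VIF = 1 / (1 - R^2). Perfectly
#' collinear columns report `Inf`. Values above 5 are conventionally
#' taken as a redundancy warning; the function reports, it does not drop.
#'
#' @param x Predictor data frame.
#' @return Data frame with columns `term` and `vif`.
#' @export
vif_check <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  cc <- stats::complete.cases(x)
  xcc <- x[cc, , drop = FALSE]
  mm <- stats::model.matrix(~ ., data = xcc)[, -1, drop = FALSE]
  keep <- apply(mm, 2L, function(v) stats::sd(v) > 0)
  mm <- mm[, keep, drop = FALSE]
  if (nrow(mm) < ncol(mm) + 2L) {
    stop("too few complete cases for VIF (need >= #terms + 2)",
         call. = FALSE)
  }
  vifs <- vapply(seq_len(ncol(mm)), function(j) {
    yj <- mm[, j]
    Xj <- cbind(1, mm[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = colnames(mm), vif = vifs, stringsAsFactors = FALSE)
}
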