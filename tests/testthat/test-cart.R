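test_that("a perfectly separable response yields one clean split", {
  x <- data.frame(g = factor(c("a", "a", "a", "b", "b", "b")))
  y <- c(0, 0, 0, 10, 10, 10)
  tree <- grow_tree(x, y, tree_hyperparams(5, 2, 0.01, 3))
  frame <- tree$fit$frame
  expect_equal(sum(frame$var == "<leaf>"), 2L)
  expect_setequal(frame$yval[frame$var == "<leaf>"], c(0, 10))
  validate_tree(tree)
})

test_that("constant responses and tiny samples give single-node trees", {
  x <- data.frame(g = factor(rep(c("a", "b"), 5)))
  tree <- grow_tree(x, rep(2.5, 10), tree_hyperparams(5, 2, 0.01, 3))
  expect_equal(nrow(tree$fit$frame), 1L)
  expect_equal(predict(tree, x), rep(2.5, 10))

  tree2 <- grow_tree(x[1:4, , drop = FALSE], c(0, 5, 0, 5),
                     tree_hyperparams(5, 2, 0.01, 3))
  expect_equal(nrow(tree2$fit$frame), 1L)
})

test_that("the root split matches the exhaustive SSE-optimal split", {
  hp <- tree_hyperparams(5, 2, 1e-9, 2)
  for (seed in 1:20) {
    inst <- random_split_instance(seed)
    oracle <- oracle_best_split(inst$x, inst$y, min_terminal = 2L)
    tree <- grow_tree(inst$x, inst$y, hp)
    if (nrow(tree$fit$frame) == 1L) next   # no admissible split improved fit
    left <- tree$node_of_row == 2L
    expect_equal(partition_reduction(inst$y, left), oracle$reduction,
                 tolerance = 1e-9,
                 label = sprintf("seed %d root-split reduction", seed))
  }
})

test_that("surrogate splits route rows missing the primary variable", {
  set.seed(4)
  n <- 60
  primary <- factor(sample(c("lo", "hi"), n, replace = TRUE))
  # perfectly agreeing continuous surrogate
  shadow <- ifelse(primary == "hi", 1, 0) + runif(n, 0, 0.05)
  y <- ifelse(primary == "hi", 4, 0) + rnorm(n, 0, 0.1)
  x <- data.frame(primary = primary, shadow = shadow)
  tree <- grow_tree(x, y, tree_hyperparams(10, 5, 0.01, 3))
  expect_identical(as.character(tree$fit$frame$var[1]), "primary")
  expect_gte(tree$fit$frame$nsurrogate[1], 1L)
  x_missing <- x
  x_missing$primary[1:10] <- NA
  expect_equal(predict(tree, x_missing)[1:10], predict(tree, x)[1:10])
})

test_that("surrogate logic is inert when nothing is missing", {
  kt <- generate_known_tree_cohort(
    120,
    regions = list(
      list(when = list(intervention = c("cam", "drug")), mean = 2),
      list(when = list(intervention = c("lifestyle",
                                        "endocrine_modification",
                                        "control")), mean = -1)),
    noise_sd = 0.8, seed = 6)
  x <- kt$x[stats::complete.cases(kt$x), , drop = FALSE]
  y <- kt$y[stats::complete.cases(kt$x)]
  hp <- tree_hyperparams(10, 4, 0.01, 4)
  with_s <- grow_tree(x, y, hp, use_surrogates = TRUE)
  without <- grow_tree(x, y, hp, use_surrogates = FALSE)
  expect_equal(predict(with_s, x), predict(without, x))
})

test_that("the leaf count is non-increasing in the complexity parameter", {
  kt <- generate_known_tree_cohort(
    200,
    regions = list(
      list(when = list(intervention = "cam"), mean = 3),
      list(when = list(intervention = c("lifestyle", "drug",
                                        "endocrine_modification",
                                        "control")), mean = 0)),
    noise_sd = 1.5, seed = 12)
  leaves <- vapply(c(0.001, 0.01, 0.05, 0.1), function(cp) {
    tree <- grow_tree(kt$x, kt$y, tree_hyperparams(10, 4, cp, 6))
    sum(tree$fit$frame$var == "<leaf>")
  }, numeric(1))
  expect_true(all(diff(leaves) <= 0))
})

test_that("node summaries report medians with bootstrap intervals", {
  x <- data.frame(g = factor(c("a", "a", "a", "b", "b", "b")))
  y <- c(1, 2, 3, 7, 7, 7)
  tree <- grow_tree(x, y, tree_hyperparams(5, 2, 0.01, 3))
  ns <- node_summary(tree, seed = 1)
  expect_setequal(ns$median, c(2, 7))
  same <- ns[ns$median == 7, ]
  expect_equal(same$interval_low, 7)     # all-equal leaf: zero width
  expect_equal(same$interval_high, 7)
})

test_that("the bootstrap interval almost always contains the leaf median", {
  set.seed(33)
  y <- rnorm(20)
  x <- data.frame(g = factor(rep("a", 20), levels = c("a", "b")))
  tree <- grow_tree(x, y, tree_hyperparams(25, 2, 0.01, 3))  # root only
  med <- median(y)
  hits <- vapply(1:100, function(s) {
    ns <- node_summary(tree, seed = s)
    ns$interval_low <= med && med <= ns$interval_high
  }, logical(1))
  expect_gte(sum(hits), 99)
})

test_that("tree structure serializes with surrogates and validates", {
  kt <- generate_known_tree_cohort(
    150,
    regions = list(
      list(when = list(intervention = c("cam", "drug")), mean = 2),
      list(when = list(intervention = c("lifestyle",
                                        "endocrine_modification",
                                        "control")), mean = -1)),
    noise_sd = 1, seed = 3, missing_rate = 0.15)
  tree <- grow_tree(kt$x, kt$y, tree_hyperparams(10, 4, 0.01, 4))
  validate_tree(tree)
  nodes <- tree_to_list(tree, boot_reps = 200, seed = 1)
  expect_equal(nodes$n, 150)
  expect_false(nodes$leaf)
  expect_equal(nodes$yes$n + nodes$no$n, nodes$n)
  txt <- tree_text(tree, boot_reps = 200, seed = 1)
  expect_true(any(grepl("yes:", txt)))
})

test_that("VIF flags collinearity and matches an independent R^2 oracle", {
  set.seed(5)
  n <- 80
  a <- rnorm(n); b <- rnorm(n)
  ortho <- vif_check(data.frame(a = a, b = b))
  expect_true(all(abs(ortho$vif - 1) < 0.2))

  dup <- vif_check(data.frame(a = a, b = b, a2 = a))
  expect_true(any(is.infinite(dup$vif)))

  cmix <- a + b + rnorm(n, 0, 0.5)
  got <- vif_check(data.frame(a = a, b = b, cmix = cmix))
  # oracle: VIFs are the diagonal of the inverse correlation matrix
  R <- stats::cor(cbind(a, b, cmix))
  expect_equal(got$vif, diag(solve(R)), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(vif_check(data.frame(a = a[1:3], b = b[1:3],
                                    c = rnorm(3), d = rnorm(3))),
               "complete cases")
})
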