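test_that("entropy follows the Shannon formula in bits", {
  expect_equal(entropy(rep("a", 8)), 0)
  expect_equal(entropy(rep(c("a", "b"), each = 4)), 1)
  expect_equal(entropy(rep(c("a", "b"), c(2, 6))), 0.8113, tolerance = 1e-4)
  expect_error(entropy(character(0)), "non-empty")
})

test_that("best_split handles the minimal and degenerate cases", {
  s <- best_split(c(-1, 1), c("A", "B"), min_cases = 1L)
  expect_equal(s$threshold, -1)
  expect_equal(s$gain, 1)
  expect_null(best_split(rep(2, 5), rep(c("A", "B"), c(2, 3)), 1L))
  expect_null(best_split(c(1, 2), c("A", "B"), min_cases = 2L))
})

test_that("best_split matches brute-force enumeration on random data", {
  set.seed(61)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    values <- round(rnorm(n), 2)
    labels <- if (i %% 2 == 0) sample(c("A", "B"), n, replace = TRUE)
              else ifelse(values > 0, "pos", "neg")
    min_cases <- sample(1:2, 1)
    got <- best_split(values, labels, min_cases)
    want <- oracle_best_split(values, labels, min_cases)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
      expect_equal(got$gain_ratio, want$gain_ratio, tolerance = 1e-12)
    }
  }
  # sign-separable labels are split perfectly
  set.seed(62)
  v <- rnorm(10)
  s <- best_split(v, ifelse(v > 0, "pos", "neg"), 1L)
  expect_equal(s$threshold, max(v[v < 0]))
  expect_equal(s$gain, entropy(ifelse(v > 0, "p", "n")))
})

test_that("grow_tree covers pure, separable and conflicting inputs", {
  pure <- grow_tree(matrix(rnorm(10), ncol = 1), rep("HC", 10))
  expect_equal(pure$root$type, "leaf")
  expect_equal(pure$root$wrong, 0L)

  set.seed(63)
  x <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1)
  y <- rep(c("neg", "pos"), each = 10)
  tree <- grow_tree(x, y)
  expect_equal(tree$root$type, "node")
  expect_equal(tree$root$left$type, "leaf")
  expect_equal(tree$root$right$type, "leaf")
  expect_equal(unname(predict(tree, x)), y)

  # identical rows with mixed labels degrade to one impure leaf, no error
  conflict <- grow_tree(matrix(1, nrow = 4, ncol = 2), c("A", "A", "B", "A"))
  expect_equal(conflict$root$type, "leaf")
  expect_equal(conflict$root$label, "A")
  expect_equal(conflict$root$wrong, 1L)

  # majority tie at a leaf goes to the lexicographically first class
  tie <- grow_tree(matrix(1, nrow = 2, ncol = 1), c("Z", "B"))
  expect_equal(tie$root$label, "B")
})

test_that("unpruned trees classify conflict-free training data perfectly", {
  set.seed(64)
  for (i in 1:5) {
    tbl <- make_score_table(
      cohort_spec(groups = c(HC = 10L, PD = 10L),
                  patterns = list(pattern_spec(means = c(PD = 1), sd = 1)),
                  seed = 70L + i),
      n_features = 6
    )
    tree <- fit_c45(tbl, min_cases = 1, prune = FALSE)
    feats <- as.matrix(dplyr::select(tbl, dplyr::starts_with("SSPC")))
    expect_equal(unname(predict(tree, feats)), tbl$label)
    expect_equal(glance(tree)$training_errors, 0L)
  }
})

test_that("pessimistic bound matches the binomial-tail oracle", {
  for (cf in c(0.1, 0.25, 0.5)) {
    for (case in list(c(0, 1), c(0, 9), c(1, 10), c(3, 12))) {
      expect_equal(ssmtree:::error_ubound(case[1], case[2], cf),
                   oracle_error_ubound(case[1], case[2], cf), tolerance = 1e-8)
    }
  }
  # classic zero-error closed form
  expect_equal(ssmtree:::error_ubound(0, 6, 0.25), 1 - 0.25^(1 / 6))
})

test_that("pruning collapses unsupported subtrees at cf = 0.25 but not cf = 1", {
  # 8 clean cases plus a B/A pair isolated by 1-case splits
  x <- matrix(1:10, ncol = 1)
  y <- c(rep("A", 8), "B", "A")
  unpruned <- grow_tree(x, y, tree_params(min_cases = 1, pruning_enabled = FALSE))
  expect_gt(ssmtree:::count_nodes(unpruned$root), 1L)

  # oracle decision at the root: pessimistic errors of the collapsed leaf
  # vs the summed leaf bounds of the subtree
  leaf_err <- 10 * oracle_error_ubound(1, 10, 0.25)
  sub_err <- 8 * oracle_error_ubound(0, 8, 0.25) + 2 * oracle_error_ubound(0, 1, 0.25)
  expect_lt(leaf_err, sub_err)

  pruned <- prune_tree(unpruned, cf = 0.25)
  expect_equal(pruned$root$type, "leaf")
  expect_equal(pruned$root$label, "A")
  expect_equal(pruned$root$wrong, 1L)

  # a pure tree and the cf = 1 limit are left untouched
  sep <- grow_tree(matrix(c(1, 2, 3), ncol = 1), c("A", "B", "A"),
                   tree_params(min_cases = 1, pruning_enabled = FALSE))
  expect_equal(glance(sep)$training_errors, 0L)
  expect_identical(prune_tree(sep, cf = 1), sep)
  expect_equal(prune_tree(sep, cf = 0.25)$root$type, "leaf")
})

test_that("pruning shrinks trees and is idempotent", {
  set.seed(65)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  y <- sample(c("A", "B"), 40, replace = TRUE)
  unpruned <- grow_tree(x, y, tree_params(min_cases = 1, pruning_enabled = FALSE))
  pruned <- prune_tree(unpruned, 0.25)
  expect_lte(ssmtree:::count_nodes(pruned$root), ssmtree:::count_nodes(unpruned$root))
  expect_identical(prune_tree(pruned, 0.25), pruned)
})

test_that("prediction descends deterministically and rejects NaN", {
  tree <- grow_tree(matrix(c(-1, 1), ncol = 1), c("A", "B"),
                    tree_params(min_cases = 1))
  # boundary value goes left; threshold is an observed value (-1)
  expect_equal(tree$root$threshold, -1)
  expect_equal(unname(predict(tree, matrix(c(-1, -0.999), ncol = 1))), c("A", "B"))
  expect_error(predict(tree, matrix(NaN, ncol = 1)), "NaN")
  expect_error(predict(tree, matrix(1, ncol = 2)), "expects")
})

test_that("predictions are covariant under positive feature scaling", {
  set.seed(66)
  x <- matrix(rnorm(30 * 2), ncol = 2)
  y <- ifelse(x[, 1] + 0.3 * rnorm(30) > 0, "pos", "neg")
  tree <- grow_tree(x, y)
  xs <- x
  xs[, 1] <- x[, 1] * 100
  tree_s <- grow_tree(xs, y)
  expect_equal(predict(tree_s, xs), predict(tree, x))
})

test_that("tree export follows the (total/misclassified) leaf convention", {
  leaf18 <- grow_tree(matrix(rnorm(18), ncol = 1), rep("HC", 18))
  expect_equal(export_tree(leaf18, "text"), "HC (18)")

  mixed <- grow_tree(matrix(1, nrow = 10, ncol = 1), rep(c("HC", "PD"), c(9, 1)))
  expect_equal(export_tree(mixed, "text"), "HC (10/1)")

  set.seed(67)
  x <- matrix(c(rnorm(9, -2), rnorm(9, 2)), ncol = 1)
  y <- rep(c("HC", "PD"), each = 9)
  tree <- grow_tree(x, y, feature_names = "SSPC5")
  txt <- export_tree(tree, "text")
  expect_match(txt, "SSPC5 <= ")
  expect_match(txt, "SSPC5 > ")
  expect_match(txt, "HC \\(9\\)")

  dot <- export_tree(tree, "dot")
  expect_match(dot, "^digraph")
  expect_equal(sum(strsplit(dot, "")[[1]] == "{"),
               sum(strsplit(dot, "")[[1]] == "}"))
  expect_match(dot, "label=\"<= ")
  expect_match(dot, "shape=box")
})

test_that("trees round-trip through plain-text serialization", {
  set.seed(68)
  x <- matrix(rnorm(30 * 4), ncol = 4)
  y <- ifelse(x[, 2] > 0.2, "MSA", "HC")
  tree <- grow_tree(x, y)
  path <- tempfile(fileext = ".yaml")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_equal(back$root, tree$root)
  expect_equal(export_tree(back, "text"), export_tree(tree, "text"))
  expect_equal(predict(back, x), predict(tree, x))
})

test_that("tidy and glance summarize tree structure", {
  set.seed(69)
  x <- matrix(c(rnorm(10, -2), rnorm(10, 2)), ncol = 1)
  tree <- grow_tree(x, rep(c("HC", "PD"), each = 10), feature_names = "SSPC1")
  nodes <- tidy(tree)
  expect_equal(sum(nodes$type == "leaf"), 2L)
  expect_equal(nodes$feature[1], "SSPC1")
  g <- glance(tree)
  expect_equal(g$root_feature, "SSPC1")
  expect_equal(g$n_cases, 20L)
})
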