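#' Shannon entropy of a label set
#'
#' @param labels Non-empty vector of class labels.
#' @return Entropy in bits of the empirical label distribution.
#' @export
entropy <- function(labels) {
  if (length(labels) == 0L) stop_ssm("`labels` must be non-empty")
  p <- tabulate(factor(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Best binary split of one continuous feature
#'
#' Evaluates every candidate threshold between consecutive distinct sorted
#' values. A candidate is admissible when both branches receive at least
#' `min_cases` cases. Among admissible candidates whose information gain is
#' at least the mean gain of all admissible candidates (the C4.5 guard
#' against spuriously high ratios on unbalanced splits), the one maximizing
#' the gain ratio (gain / split information) wins; ratio ties resolve to
#' the smallest threshold. The reported threshold is the largest observed
#' value not exceeding the bracketing midpoint, so thresholds always
#' appear in the data.
#'
#' @param values Numeric feature values.
#' @param labels Class labels, same length.
#' @param min_cases Minimum branch size.
#' @return `NULL` if no admissible split exists; else a list with
#'   `threshold`, `gain` (bits), `gain_ratio`.
#' @export
best_split <- function(values, labels, min_cases = 2L) {
  n <- length(values)
  if (n != length(labels)) stop_ssm("`values` and `labels` differ in length")
  if (n < 2L) return(NULL)
  ord <- order(values)
  v <- values[ord]
  f <- factor(labels[ord])
  # cumulative class counts over the sorted order: one pass gives every
  # candidate's left/right counts
  ind <- matrix(0L, nrow = n, ncol = nlevels(f))
  ind[cbind(seq_len(n), as.integer(f))] <- 1L
  cum <- ind
  for (j in seq_len(ncol(ind))) cum[, j] <- cumsum(ind[, j])
  cut_at <- which(v[-n] < v[-1])        # boundaries between distinct values
  n_l <- cut_at
  n_r <- n - n_l
  admissible <- n_l >= min_cases & n_r >= min_cases
  cut_at <- cut_at[admissible]
  if (length(cut_at) == 0L) return(NULL)
  n_l <- n_l[admissible]
  n_r <- n_r[admissible]
  count_entropy <- function(counts, totals) {
    p <- counts / totals
    plog <- p * log2(p)
    plog[p == 0] <- 0
    -rowSums(plog)
  }
  total <- cum[n, ]
  left_counts <- cum[cut_at, , drop = FALSE]
  right_counts <- rep(total, each = length(cut_at)) - left_counts
  h_parent <- count_entropy(matrix(total, nrow = 1), n)
  gain <- h_parent - (n_l * count_entropy(left_counts, n_l) +
                        n_r * count_entropy(right_counts, n_r)) / n
  p_l <- n_l / n
  split_info <- -p_l * log2(p_l) - (1 - p_l) * log2(1 - p_l)
  # C4.5 guard: only candidates with at-least-average gain may win on
  # ratio; ratio ties (within 1e-12) resolve to the smallest threshold
  eligible <- which(gain >= mean(gain) - 1e-12)
  ratio <- gain[eligible] / split_info[eligible]
  best <- eligible[which(ratio >= max(ratio) - 1e-12)[1]]
  list(
    threshold = v[cut_at[best]],        # largest observed value <= midpoint
    gain = gain[best],
    gain_ratio = gain[best] / split_info[best]
  )
}

#' C4.5 tree parameters
#'
#' @param min_cases Minimum number of cases required in each of at least
#'   two branches of a split (C4.5 default 2).
#' @param cf Pruning confidence in (0, 1]; smaller values prune harder
#'   (C4.5 default 0.25).
#' @param pruning_enabled Apply pessimistic pruning after growth.
#' @return A `tree_params` list.
#' @export
tree_params <- function(min_cases = 2L, cf = 0.25, pruning_enabled = TRUE) {
  if (min_cases < 1L) stop_ssm("`min_cases` must be >= 1")
  if (cf <= 0 || cf > 1) stop_ssm("`cf` must be in (0, 1]")
  structure(
    list(
      min_cases = as.integer(min_cases),
      cf = cf,
      pruning_enabled = isTRUE(pruning_enabled)
    ),
    class = "tree_params"
  )
}

class_counts <- function(labels, classes) {
  tab <- table(factor(labels, levels = classes))
  as.integer(tab)
}

majority_label <- function(counts, classes) {
  # tie -> lexicographically first (classes are kept sorted)
  classes[which.max(counts)]
}

make_leaf <- function(labels, classes) {
  counts <- class_counts(labels, classes)
  label <- majority_label(counts, classes)
  list(
    type = "leaf",
    label = label,
    n = length(labels),
    wrong = length(labels) - max(counts),
    counts = counts
  )
}

grow_node <- function(features, labels, classes, params, depth = 0L) {
  n <- length(labels)
  if (length(unique(labels)) == 1L || n < 2L * params$min_cases) {
    return(make_leaf(labels, classes))
  }
  splits <- lapply(seq_len(ncol(features)), function(j) {
    best_split(features[, j], labels, params$min_cases)
  })
  ok <- which(!vapply(splits, is.null, logical(1)))
  if (length(ok) == 0L) return(make_leaf(labels, classes))
  ratios <- vapply(splits[ok], `[[`, numeric(1), "gain_ratio")
  j <- ok[which.max(ratios)]        # tie -> lowest feature index
  thr <- splits[[j]]$threshold
  left <- features[, j] <= thr
  counts <- class_counts(labels, classes)
  list(
    type = "node",
    feature = j,
    threshold = thr,
    n = n,
    wrong = n - max(counts),
    counts = counts,
    left = grow_node(features[left, , drop = FALSE], labels[left], classes, params, depth + 1L),
    right = grow_node(features[!left, , drop = FALSE], labels[!left], classes, params, depth + 1L)
  )
}

#' Grow a C4.5 decision tree on subject scores
#'
#' Recursive partitioning on continuous features with gain-ratio splits
#' (see [best_split()]). Recursion stops at pure nodes, when no admissible
#' split exists, or when fewer than `2 * min_cases` cases remain; each leaf
#' predicts its majority class (ties broken towards the lexicographically
#' first class). With `pruning_enabled`, [prune_tree()] is applied before
#' returning.
#'
#' `fit_c45()` is the data-frame interface: it takes a score table (as from
#' [score_table()] or [make_score_table()]) with a `label` column and uses
#' all other numeric columns as features.
#'
#' @param features Numeric matrix, M x K (rows = cases).
#' @param labels Class labels, length M.
#' @param params A [tree_params()].
#' @param feature_names Optional feature names (default `SSPC1..K` or the
#'   matrix column names).
#' @return A `c45_tree`.
#' @export
grow_tree <- function(features, labels, params = tree_params(),
                      feature_names = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop_ssm("need at least 2 cases")
  if (nrow(features) != length(labels)) {
    stop_ssm("`features` rows and `labels` differ in length")
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  feature_names <- feature_names %||% colnames(features) %||%
    paste0("SSPC", seq_len(ncol(features)))
  root <- grow_node(features, labels, classes, params)
  tree <- structure(
    list(
      root = root,
      feature_names = feature_names,
      classes = classes,
      params = params
    ),
    class = "c45_tree"
  )
  if (params$pruning_enabled) tree <- prune_tree(tree, params$cf) else tree
}

#' @rdname grow_tree
#' @param data Data frame with a label column and numeric feature columns.
#' @param label_col Name of the label column.
#' @param min_cases,cf,prune Convenience access to [tree_params()].
#' @export
fit_c45 <- function(data, label_col = "label", min_cases = 2L, cf = 0.25,
                    prune = TRUE) {
  if (!label_col %in% names(data)) {
    stop_ssm("`data` has no column '", label_col, "'")
  }
  feats <- dplyr::select(data, dplyr::where(is.numeric))
  if ("subject_id" %in% names(feats)) feats$subject_id <- NULL
  grow_tree(
    as.matrix(feats), data[[label_col]],
    params = tree_params(min_cases, cf, prune),
    feature_names = names(feats)
  )
}

# Upper confidence bound on the true error rate given E errors in N cases.
# Exact inversion of the binomial tail: the largest p with
# P(X <= E | N, p) >= 1 - cf, i.e. qbeta(1 - cf, E + 1, N - E); for E = 0
# this is 1 - cf^(1/N), the classic C4.5 zero-error case. The bound is
# clamped at the observed rate E/N so that cf = 1 reduces to the observed
# error (no pessimism, hence no pruning).
error_ubound <- function(e, n, cf) {
  if (n == 0L) return(0)
  u <- if (e >= n) 1 else qbeta(1 - cf, e + 1, n - e)
  max(u, e / n)
}

subtree_pessimistic_errors <- function(node, cf) {
  if (node$type == "leaf") {
    node$n * error_ubound(node$wrong, node$n, cf)
  } else {
    subtree_pessimistic_errors(node$left, cf) +
      subtree_pessimistic_errors(node$right, cf)
  }
}

prune_node <- function(node, classes, cf) {
  if (node$type == "leaf") return(node)
  node$left <- prune_node(node$left, classes, cf)
  node$right <- prune_node(node$right, classes, cf)
  leaf_err <- node$n * error_ubound(node$wrong, node$n, cf)
  sub_err <- subtree_pessimistic_errors(node, cf)
  if (leaf_err <= sub_err + 1e-12) {
    list(
      type = "leaf",
      label = majority_label(node$counts, classes),
      n = node$n,
      wrong = node$wrong,
      counts = node$counts
    )
  } else {
    node
  }
}

#' Pessimistic error pruning
#'
#' Bottom-up: a subtree is replaced by a leaf whenever the pessimistic
#' error estimate of the leaf (case count times the upper confidence bound
#' of its error rate at confidence `cf`) does not exceed the summed
#' pessimistic errors of the subtree's leaves. At `cf = 1` the bound equals
#' the observed error and nothing that helps on the training data is
#' pruned. Pruning is idempotent and never increases the node count.
#'
#' @param tree A `c45_tree`.
#' @param cf Pruning confidence in (0, 1].
#' @return The pruned `c45_tree`.
#' @export
prune_tree <- function(tree, cf = tree$params$cf) {
  tree$root <- prune_node(tree$root, tree$classes, cf)
  tree
}

descend <- function(node, x) {
  while (node$type == "node") {
    v <- x[node$feature]
    if (is.na(v)) stop_ssm("NaN/NA feature value encountered during prediction")
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$label
}

#' Predict classes with a C4.5 tree
#'
#' Deterministic descent: at each interior node, go to the left branch iff
#' the feature value is `<=` the threshold.
#'
#' @param object A `c45_tree`.
#' @param newdata Numeric matrix or data frame of feature rows (score
#'   columns matched by position against the training features), or a
#'   single feature vector.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[vapply(newdata, is.numeric, logical(1))])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$feature_names)) {
    stop_ssm("`newdata` has ", ncol(newdata), " features; tree expects ",
             length(object$feature_names))
  }
  vapply(seq_len(nrow(newdata)), function(i) descend(object$root, newdata[i, ]),
         character(1))
}

count_nodes <- function(node) {
  if (node$type == "leaf") 1L else 1L + count_nodes(node$left) + count_nodes(node$right)
}

leaf_text <- function(node) {
  if (node$wrong > 0L) {
    sprintf("%s (%d/%d)", node$label, node$n, node$wrong)
  } else {
    sprintf("%s (%d)", node$label, node$n)
  }
}

render_node <- function(node, feature_names, depth) {
  pad <- paste(rep("|  ", depth), collapse = "")
  if (node$type == "leaf") return(paste0(pad, leaf_text(node)))
  fname <- feature_names[node$feature]
  thr <- format(node$threshold, digits = 6)
  branch <- function(child, op) {
    head_line <- paste0(pad, fname, " ", op, " ", thr)
    if (child$type == "leaf") {
      paste0(head_line, ": ", leaf_text(child))
    } else {
      c(head_line, render_node(child, feature_names, depth + 1L))
    }
  }
  c(branch(node$left, "<="), branch(node$right, ">"))
}

#' Export a decision tree as text or Graphviz DOT
#'
#' The text rendering mirrors the field's usual tree drawings: interior
#' nodes named by feature (e.g. `SSPC5`), branch conditions `<= t` / `> t`,
#' and leaves as `CLASS (n)` or `CLASS (n/m)` where `m` counts
#' misclassified training cases at that leaf.
#'
#' @param tree A `c45_tree`.
#' @param format `"text"` or `"dot"`.
#' @return A single string.
#' @export
export_tree <- function(tree, format = c("text", "dot")) {
  format <- match.arg(format)
  if (format == "text") {
    if (tree$root$type == "leaf") return(leaf_text(tree$root))
    return(paste(render_node(tree$root, tree$feature_names, 0L), collapse = "\n"))
  }
  lines <- c("digraph c45_tree {", "  node [fontname=\"Helvetica\"];")
  counter <- new.env()
  counter$i <- 0L
  emit <- function(node) {
    counter$i <- counter$i + 1L
    id <- paste0("n", counter$i)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf("  %s [shape=box, label=\"%s\"];", id, leaf_text(node)))
      return(id)
    }
    lines <<- c(lines, sprintf("  %s [shape=oval, label=\"%s\"];", id,
                               tree$feature_names[node$feature]))
    thr <- format(node$threshold, digits = 6)
    idl <- emit(node$left)
    idr <- emit(node$right)
    lines <<- c(
      lines,
      sprintf("  %s -> %s [label=\"<= %s\"];", id, idl, thr),
      sprintf("  %s -> %s [label=\"> %s\"];", id, idr, thr)
    )
    id
  }
  emit(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.c45_tree <- function(x, ...) {
  cat("<c45_tree> ", count_nodes(x$root), " nodes, classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  cat(export_tree(x, "text"), "\n")
  invisible(x)
}

tidy_node <- function(node, feature_names, id, parent, branch) {
  is_split <- node$type == "node"
  row <- tibble::new_tibble(list(
    node = id,
    parent = parent,
    branch = branch,
    type = node$type,
    feature = if (is_split) feature_names[[node$feature]] else NA_character_,
    threshold = if (is_split) node$threshold else NA_real_,
    label = if (is_split) NA_character_ else node$label,
    n = as.integer(node$n),
    wrong = as.integer(node$wrong)
  ), nrow = 1L)
  if (node$type == "leaf") return(list(rows = row, next_id = id + 1L))
  l <- tidy_node(node$left, feature_names, id + 1L, id, "<=")
  r <- tidy_node(node$right, feature_names, l$next_id, id, ">")
  list(rows = dplyr::bind_rows(row, l$rows, r$rows), next_id = r$next_id)
}

#' @describeIn grow_tree One row per tree node (preorder), with parent
#'   links, split feature/threshold, leaf label and case counts.
#' @param x,object A `c45_tree`.
#' @param ... Unused.
#' @export
tidy.c45_tree <- function(x, ...) {
  tidy_node(x$root, x$feature_names, 1L, NA_integer_, NA_character_)$rows
}

#' @describeIn grow_tree One-row summary: node/leaf counts, training
#'   misclassifications, root feature.
#' @export
glance.c45_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(
    n_nodes = nrow(nodes),
    n_leaves = sum(nodes$type == "leaf"),
    n_cases = x$root$n,
    training_errors = sum(nodes$wrong[nodes$type == "leaf"]),
    root_feature = if (x$root$type == "node")
      x$feature_names[x$root$feature] else NA_character_
  )
}

#' Save / load a decision tree
#'
#' Plain-text YAML serialization of the full node structure; round-trips
#' exactly (structure, thresholds, counts, predictions).
#'
#' @param tree A `c45_tree`.
#' @param path File path.
#' @return `path` invisibly; `read_tree()` returns the `c45_tree`.
#' @export
write_tree <- function(tree, path) {
  payload <- list(
    feature_names = tree$feature_names,
    classes = tree$classes,
    params = unclass(tree$params),
    root = tree$root
  )
  writeLines(yaml::as.yaml(payload, precision = 17L), path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  p <- yaml::read_yaml(path)
  fix <- function(node) {
    node$counts <- as.integer(unlist(node$counts))
    node$n <- as.integer(node$n)
    node$wrong <- as.integer(node$wrong)
    if (node$type == "node") {
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  structure(
    list(
      root = fix(p$root),
      feature_names = unlist(p$feature_names),
      classes = unlist(p$classes),
      params = tree_params(p$params$min_cases, p$params$cf, p$params$pruning_enabled)
    ),
    class = "c45_tree"
  )
}
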