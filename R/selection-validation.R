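#' Feature (component) preselection rule
#'
#' @param mode `"all"` (every component), `"variance_fraction"` (the first
#'   `ceiling(amount * K)` components in eigenvalue order), or `"aic_best"`
#'   (the `amount` best components by [rank_components_aic()]).
#' @param amount Fraction in (0, 1] for `variance_fraction`; a positive
#'   integer count for `aic_best`; ignored for `all`.
#' @return A `selection_spec`.
#' @export
selection_spec <- function(mode = c("all", "variance_fraction", "aic_best"),
                           amount = NULL) {
  mode <- match.arg(mode)
  if (mode == "variance_fraction") {
    if (is.null(amount) || amount <= 0 || amount > 1) {
      stop_ssm("`amount` must be a fraction in (0, 1] for variance_fraction")
    }
  } else if (mode == "aic_best") {
    if (is.null(amount) || amount < 1) {
      stop_ssm("`amount` must be an integer >= 1 for aic_best")
    }
    amount <- as.integer(amount)
  }
  structure(list(mode = mode, amount = amount), class = "selection_spec")
}

#' Rank components by single-feature classifier AIC
#'
#' For each score component independently, a two-class Gaussian classifier
#' is fit by maximum likelihood: class-conditional means and a pooled
#' variance (k = 3 parameters), with empirical class priors. Its AIC is
#' 2k - 2 ln L, where L is the classifier's likelihood of the observed
#' labels — the product over subjects of the posterior probability the
#' model assigns to each subject's true class. This makes the ranking
#' scale-invariant (PCA components have wildly different score variances)
#' and measures exactly what preselection needs: how well the component
#' alone predicts the diagnosis. Components are returned best (lowest AIC)
#' first; zero-variance components rank last.
#'
#' @param scores M x K numeric matrix of subject scores.
#' @param labels Binary class labels, length M.
#' @return Integer vector of component indices, best first.
#' @export
rank_components_aic <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop_ssm("AIC ranking requires exactly two classes, got ", length(classes))
  }
  y <- match(labels, classes)
  priors <- tabulate(y, 2L) / length(y)
  aic <- vapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    mu <- vapply(1:2, function(cl) mean(x[y == cl]), numeric(1))
    sigma2 <- mean((x - mu[y])^2)       # pooled MLE variance
    if (sigma2 < 1e-300) return(Inf)    # degenerate: rank last
    dens <- vapply(1:2, function(cl) {
      priors[cl] * dnorm(x, mu[cl], sqrt(sigma2))
    }, numeric(length(x)))
    post <- dens[cbind(seq_along(x), y)] / rowSums(dens)
    2 * 3 - 2 * sum(log(post))
  }, numeric(1))
  order(aic)
}

#' Select score components for classification
#'
#' @param scores An `ssm_model` or an M x K score matrix (columns in
#'   eigenvalue order).
#' @param spec A [selection_spec()].
#' @param labels Class labels (required for `aic_best`).
#' @return Integer vector of selected component indices.
#' @export
select_features <- function(scores, spec, labels = NULL) {
  if (inherits(scores, "ssm_model")) {
    labels <- labels %||% scores$labels
    scores <- scores$scores
  }
  k <- ncol(scores)
  switch(spec$mode,
    all = seq_len(k),
    variance_fraction = seq_len(min(k, ceiling(spec$amount * k))),
    aic_best = {
      if (spec$amount > k) {
        stop_ssm("requested ", spec$amount, " components but only ", k, " exist")
      }
      rank_components_aic(scores, labels)[seq_len(spec$amount)]
    }
  )
}

#' Classification metrics from a confusion matrix
#'
#' Performance is the percentage of correct classifications. In the binary
#' case the convention of the source tables is kept: sensitivity is the
#' percentage of the reference group (`healthy_label`, e.g. healthy
#' controls — or the first disease group in disease-vs-disease runs)
#' correctly classified, and specificity the percentage of the remaining
#' (patient) rows correctly classified. With more than two classes only
#' per-class accuracies are defined.
#'
#' @param confusion Square count matrix, rows = truth, columns = predicted.
#' @param healthy_label Row name of the reference group; default the
#'   lexicographically first class.
#' @return List with `performance`, `sensitivity`, `specificity` (both
#'   `NA` unless binary), `per_class_accuracy` (named vector, %).
#' @export
compute_metrics <- function(confusion, healthy_label = NULL) {
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0L) stop_ssm("`confusion` is empty")
  if (nrow(confusion) != ncol(confusion)) stop_ssm("`confusion` must be square")
  if (is.null(rownames(confusion))) {
    rownames(confusion) <- colnames(confusion) <- paste0("class", seq_len(nrow(confusion)))
  }
  total <- sum(confusion)
  correct <- diag(confusion)
  row_tot <- rowSums(confusion)
  per_class <- 100 * correct / row_tot
  performance <- 100 * sum(correct) / total
  sensitivity <- specificity <- NA_real_
  if (nrow(confusion) == 2L) {
    healthy_label <- healthy_label %||% sort(rownames(confusion))[1]
    if (!healthy_label %in% rownames(confusion)) {
      stop_ssm("`healthy_label` '", healthy_label, "' is not a confusion row")
    }
    patient <- setdiff(rownames(confusion), healthy_label)
    sensitivity <- 100 * confusion[healthy_label, healthy_label] / row_tot[healthy_label]
    specificity <- 100 * sum(diag(confusion)[patient]) / sum(row_tot[patient])
  }
  list(
    performance = performance,
    sensitivity = unname(sensitivity),
    specificity = unname(specificity),
    per_class_accuracy = per_class
  )
}

new_cv_result <- function(subject_ids, truth, pred, healthy_label = NULL) {
  classes <- sort(union(truth, pred))
  confusion <- unclass(table(
    truth = factor(truth, levels = classes),
    predicted = factor(pred, levels = classes)
  ))
  metrics <- compute_metrics(confusion, healthy_label)
  structure(
    list(
      predictions = tibble::tibble(
        subject_id = subject_ids, truth = truth, predicted = pred,
        correct = truth == pred
      ),
      confusion = confusion,
      performance = metrics$performance,
      sensitivity = metrics$sensitivity,
      specificity = metrics$specificity,
      per_class_accuracy = metrics$per_class_accuracy,
      healthy_label = healthy_label %||%
        (if (length(classes) == 2L) classes[1] else NA_character_)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> performance ", sprintf("%.1f%%", x$performance), sep = "")
  if (!is.na(x$sensitivity)) {
    cat(sprintf(", sensitivity %.1f%%, specificity %.1f%%",
                x$sensitivity, x$specificity))
  }
  cat("\nconfusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' @describeIn loocv Per-subject predictions as a tibble.
#' @param x,object A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @describeIn loocv One-row metric summary (%, 1-decimal semantics of the
#'   usual tables preserved by the caller).
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$predictions),
    performance = x$performance,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' @describeIn loocv Confusion-matrix heatmap.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$confusion))
  names(d) <- c("truth", "predicted", "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}

#' Per-fold feature extraction for leave-one-out validation
#'
#' For every subject, removes that subject, rebuilds the intensity mask and
#' refits the SSM/PCA model on the remaining N - 1 volumes, and projects
#' the held-out subject onto the fold's patterns. The held-out subject's
#' voxel data influence nothing on the training side — not the mask, the
#' GMP, the patterns, nor (later) feature selection.
#'
#' @param volumes List of [brain_volume()]s.
#' @param labels Class labels, one per volume.
#' @param threshold_fraction Mask threshold.
#' @return List of folds, each with `test_index`, `model` (the fold's
#'   `ssm_model`), and `test_scores` (projection of the held-out subject).
#' @export
extract_folds <- function(volumes, labels, threshold_fraction = 0.35) {
  m <- length(volumes)
  lapply(seq_len(m), function(i) {
    train <- build_data_matrix(volumes[-i], labels[-i], threshold_fraction)
    model <- fit_ssm(train)
    list(
      test_index = i,
      model = model,
      test_scores = project_subject(model, volumes[[i]])
    )
  })
}

classify_folds <- function(folds, labels, classifier, selection) {
  all_classes <- unique(labels)
  vapply(folds, function(fold) {
    i <- fold$test_index
    train_labels <- labels[-i]
    missing <- setdiff(all_classes, unique(train_labels))
    if (length(missing) > 0L) {
      warning("class ", paste(missing, collapse = ", "),
              " absent from training fold ", i, call. = FALSE)
    }
    sel <- select_features(fold$model$scores, selection, train_labels)
    model <- fit_classifier(classifier, fold$model$scores[, sel, drop = FALSE],
                            train_labels)
    predict_all(model, matrix(fold$test_scores[sel], nrow = 1L))
  }, character(1))
}

#' Leave-one-out cross validation with per-fold feature re-extraction
#'
#' Because PCA subject scores depend on the whole dataset, every fold
#' re-runs the complete feature extraction on the N - 1 training subjects:
#' mask, SSM/PCA fit, component selection and classifier training all see
#' only the training fold; the held-out subject is projected onto the
#' fold's patterns and classified. Performance is the percentage of
#' correct classifications over the N repetitions.
#'
#' @param volumes List of [brain_volume()]s (M >= 3, every class with at
#'   least 2 members).
#' @param labels Class labels, one per volume.
#' @param classifier A [classifier_spec()].
#' @param selection A [selection_spec()].
#' @param threshold_fraction Mask threshold.
#' @param healthy_label Reference group for sensitivity/specificity, see
#'   [compute_metrics()].
#' @param folds Optionally a precomputed [extract_folds()] result (the
#'   extraction is label-independent, so it can be reused across label
#'   permutations).
#' @return A `cv_result`.
#' @export
loocv <- function(volumes, labels, classifier = classifier_spec("c45"),
                  selection = selection_spec("all"),
                  threshold_fraction = 0.35, healthy_label = NULL,
                  folds = NULL) {
  labels <- as.character(labels)
  if (length(volumes) < 3L) stop_ssm("need at least 3 subjects")
  if (any(table(labels) < 2L)) {
    stop_ssm("every class needs at least 2 members for leave-one-out")
  }
  folds <- folds %||% extract_folds(volumes, labels, threshold_fraction)
  pred <- classify_folds(folds, labels, classifier, selection)
  ids <- vapply(volumes, `[[`, character(1), "subject_id")
  new_cv_result(ids, labels, pred, healthy_label)
}

#' Leave-one-out cross validation on a fixed score table
#'
#' Fast, mildly optimistic variant: subject scores are taken as given
#' (typically from one model fit on all subjects) and only the classifier
#' is refit per fold. This is the shortcut used for broad classifier
#' comparisons; for unbiased estimates use [loocv()], which re-extracts
#' features per fold.
#'
#' @param data Score table: tibble/data frame with a `label` column and
#'   numeric score columns (plus optional `subject_id`).
#' @param classifier A [classifier_spec()].
#' @param selection A [selection_spec()]; selection is re-run inside each
#'   fold on the training rows only.
#' @param healthy_label Reference group for sensitivity/specificity.
#' @return A `cv_result`.
#' @export
loocv_scores <- function(data, classifier = classifier_spec("c45"),
                         selection = selection_spec("all"),
                         healthy_label = NULL) {
  labels <- as.character(data$label)
  ids <- if ("subject_id" %in% names(data)) data$subject_id else
    paste0("s", seq_len(nrow(data)))
  feats <- dplyr::select(data, dplyr::where(is.numeric))
  scores <- as.matrix(feats)
  pred <- vapply(seq_len(nrow(scores)), function(i) {
    sel <- select_features(scores[-i, , drop = FALSE], selection, labels[-i])
    model <- fit_classifier(classifier, scores[-i, sel, drop = FALSE], labels[-i])
    predict_all(model, scores[i, sel, drop = FALSE])
  }, character(1))
  new_cv_result(ids, labels, pred, healthy_label)
}

#' Permutation test of leave-one-out performance
#'
#' The observed performance P_O is the [loocv()] result on the true
#' labels. Each of `n_perm` iterations shuffles the labels uniformly at
#' random and reruns the cross validation; the p value is the fraction of
#' null performances P_i with P_i >= P_O. Results with p < 0.05 are
#' conventionally called significant. Feature extraction (mask, SSM/PCA,
#' projection) does not depend on labels, so the per-fold models are
#' computed once and reused across permutations — the resulting
#' predictions are identical to re-running the full per-fold refit for
#' every permuted labelling.
#'
#' @inheritParams loocv
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @return A `permutation_result`: list with `observed`,
#'   `null_performances`, `p_value`, `n_perm`, `seed`, and the observed
#'   `cv` result.
#' @export
permutation_test <- function(volumes, labels, classifier = classifier_spec("c45"),
                             selection = selection_spec("all"),
                             n_perm = 100L, seed = 1L,
                             threshold_fraction = 0.35, healthy_label = NULL) {
  if (n_perm < 1L) stop_ssm("`n_perm` must be >= 1")
  labels <- as.character(labels)
  folds <- extract_folds(volumes, labels, threshold_fraction)
  observed_cv <- loocv(volumes, labels, classifier, selection,
                       threshold_fraction, healthy_label, folds = folds)
  ids <- vapply(volumes, `[[`, character(1), "subject_id")
  null_perf <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- sample(labels)
    pred <- suppressWarnings(classify_folds(folds, perm, classifier, selection))
    new_cv_result(ids, perm, pred)$performance
  }, numeric(1)))
  structure(
    list(
      observed = observed_cv$performance,
      null_performances = null_perf,
      p_value = mean(null_perf >= observed_cv$performance),
      n_perm = as.integer(n_perm),
      seed = as.integer(seed),
      cv = observed_cv
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.1f%%, p = %.2f (%d permutations, seed %d)\n",
    x$observed, x$p_value, x$n_perm, x$seed
  ))
  invisible(x)
}

#' @describeIn permutation_test One-row summary.
#' @param x,object A `permutation_result`.
#' @param ... Unused.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    p_value = x$p_value,
    n_perm = x$n_perm,
    null_mean = mean(x$null_performances),
    null_max = max(x$null_performances)
  )
}

#' @describeIn permutation_test Null-performance histogram with the
#'   observed performance marked.
#' @export
autoplot.permutation_result <- function(object, ...) {
  d <- tibble::tibble(performance = object$null_performances)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$performance)) +
    ggplot2::geom_histogram(binwidth = 5, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "null LOOCV performance (%)", y = "count") +
    ggplot2::theme_minimal()
}
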