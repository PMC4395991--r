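#' Specify a comparison classifier
#'
#' One constructor for the whole comparison harness. `c45` is the
#' package's own tree inducer; the others are the usual baselines: k
#' nearest neighbours, linear discriminant analysis, Gaussian naive Bayes,
#' CART (Gini), random forest (bagging plus random feature subsets, trees
#' unpruned), and a maximum-margin linear separator (linear-kernel SVM).
#'
#' @param method One of `"c45"`, `"knn"`, `"lda"`, `"naive_bayes"`,
#'   `"cart"`, `"random_forest"`, `"linear_margin"`. (The argument is named
#'   `method` so short hyperparameter names like `k` cannot partially match
#'   it.)
#' @param ... Hyperparameters; unknown names are rejected. Recognized:
#'   `min_cases`, `cf`, `prune` (c45); `k` (knn, default 1); `ridge`,
#'   `drop_fraction` (lda: ridge scale for the pooled covariance, default
#'   1e-6, and optional fraction of trailing features to drop, e.g. 0.1 to
#'   use only 90% of features); `n_trees`, `seed` (random_forest, defaults
#'   100 and 1); `cost` (linear_margin, default 1).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(method = c("c45", "knn", "lda", "naive_bayes",
                                       "cart", "random_forest", "linear_margin"),
                            ...) {
  kind <- match.arg(method)
  hyper <- list(...)
  allowed <- switch(kind,
    c45 = c("min_cases", "cf", "prune"),
    knn = "k",
    lda = c("ridge", "drop_fraction"),
    naive_bayes = character(0),
    cart = character(0),
    random_forest = c("n_trees", "seed"),
    linear_margin = "cost"
  )
  bad <- setdiff(names(hyper), allowed)
  if (length(bad) > 0L) {
    stop_ssm("unknown hyperparameter(s) for '", kind, "': ",
             paste(bad, collapse = ", "))
  }
  structure(list(kind = kind, hyper = hyper), class = "classifier_spec")
}

#' Fit a comparison classifier
#'
#' @param spec A [classifier_spec()].
#' @param features Numeric matrix (M x K).
#' @param labels Class labels, length M, at least 2 classes.
#' @return A fitted `ssm_classifier` handle for [predict_all()].
#' @export
fit_classifier <- function(spec, features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_ssm("need at least 2 classes")
  h <- spec$hyper
  fit <- switch(spec$kind,
    c45 = grow_tree(
      features, labels,
      params = tree_params(h$min_cases %||% 2L, h$cf %||% 0.25, h$prune %||% TRUE)
    ),
    knn = list(x = features, y = labels, k = h$k %||% 1L),
    lda = fit_lda(features, labels, classes,
                  ridge = h$ridge %||% 1e-6,
                  drop_fraction = h$drop_fraction %||% 0),
    naive_bayes = e1071::naiveBayes(
      x = as.data.frame(features), y = factor(labels, levels = classes)
    ),
    cart = rpart::rpart(
      label ~ ., data = data.frame(features, label = factor(labels, levels = classes)),
      method = "class",
      # cohorts here are tens of subjects: rpart's default minsplit = 20
      # would refuse to split at all and degenerate to the majority class
      control = rpart::rpart.control(minsplit = 4L, minbucket = 2L)
    ),
    random_forest = {
      seed <- h$seed %||% 1L
      withr::with_seed(seed, randomForest::randomForest(
        x = as.data.frame(features), y = factor(labels, levels = classes),
        ntree = h$n_trees %||% 100L
      ))
    },
    linear_margin = e1071::svm(
      x = features, y = factor(labels, levels = classes),
      kernel = "linear", cost = h$cost %||% 1, scale = FALSE
    )
  )
  structure(
    list(kind = spec$kind, fit = fit, classes = classes, n_features = ncol(features)),
    class = "ssm_classifier"
  )
}

# Gaussian linear discriminant with ridge-regularized pooled covariance
# (lambda = ridge * mean diagonal), needed because the number of score
# features can approach the number of subjects. drop_fraction > 0 instead
# drops that fraction of trailing features before fitting (the
# lowest-variance components), the alternative the comparison tables use.
fit_lda <- function(features, labels, classes, ridge = 1e-6, drop_fraction = 0) {
  keep <- seq_len(max(1L, floor((1 - drop_fraction) * ncol(features))))
  features <- features[, keep, drop = FALSE]
  mats <- lapply(classes, function(cl) features[labels == cl, , drop = FALSE])
  means <- lapply(mats, colMeans)
  n <- nrow(features)
  pooled <- Reduce(`+`, lapply(mats, function(m) {
    crossprod(sweep(m, 2L, colMeans(m)))
  })) / (n - length(classes))
  if (ridge > 0) {
    pooled <- pooled + diag(ridge * mean(diag(pooled)), ncol(pooled))
  }
  cov_inv <- tryCatch(solve(pooled), error = function(e) {
    stop_ssm("pooled covariance is singular; increase `ridge` or drop features ",
             "(`drop_fraction`)")
  })
  priors <- vapply(mats, nrow, numeric(1)) / n
  list(means = means, cov_inv = cov_inv, priors = priors,
       classes = classes, keep = keep)
}

predict_lda <- function(fit, features) {
  features <- features[, fit$keep, drop = FALSE]
  disc <- vapply(seq_along(fit$classes), function(i) {
    mu <- fit$means[[i]]
    d <- sweep(features, 2L, mu)
    -0.5 * rowSums((d %*% fit$cov_inv) * d) + log(fit$priors[i])
  }, numeric(nrow(features)))
  disc <- matrix(disc, nrow = nrow(features))
  # which.max takes the first maximum: ties go to the lexicographically
  # first class since fit$classes is sorted
  fit$classes[apply(disc, 1L, which.max)]
}

predict_knn <- function(fit, features) {
  k <- min(fit$k, nrow(fit$x))
  vapply(seq_len(nrow(features)), function(i) {
    d <- sqrt(colSums((t(fit$x) - features[i, ])^2))
    nn <- order(d)[seq_len(k)]          # stable: distance then index
    votes <- sort(table(fit$y[nn]), decreasing = TRUE)
    top <- names(votes[votes == votes[1]])
    sort(top)[1]                        # tie -> lexicographically first
  }, character(1))
}

#' Predict with a fitted comparison classifier
#'
#' @param model An `ssm_classifier` from [fit_classifier()].
#' @param features Numeric matrix with the training feature width.
#' @return Character vector of labels, one per row (empty input gives an
#'   empty vector).
#' @export
predict_all <- function(model, features) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(character(0))
  if (ncol(features) != model$n_features) {
    stop_ssm("`features` has ", ncol(features), " columns; model expects ",
             model$n_features)
  }
  switch(model$kind,
    c45 = predict(model$fit, features),
    knn = predict_knn(model$fit, features),
    lda = predict_lda(model$fit, features),
    naive_bayes = as.character(predict(model$fit, as.data.frame(features))),
    cart = as.character(predict(model$fit, data.frame(features), type = "class")),
    random_forest = as.character(predict(model$fit, as.data.frame(features))),
    linear_margin = as.character(predict(model$fit, features))
  )
}

#' Compare classifiers on precomputed score tables
#'
#' Runs [loocv_scores()] for every classifier on every dataset and lays
#' the results out as one row per classifier, one performance column per
#' dataset — the usual side-by-side comparison table. Scores here come
#' from a single model fit on all subjects, so this inherits the (mild,
#' documented) optimism of that shortcut.
#'
#' @param datasets Named list of score tables (tibbles with `label` and
#'   score columns).
#' @param specs Named list of [classifier_spec()]s.
#' @return Tibble: `classifier` plus one performance (%) column per
#'   dataset.
#' @export
compare_classifiers <- function(datasets, specs) {
  rows <- purrr::imap(specs, function(spec, spec_name) {
    perf <- purrr::map_dbl(datasets, function(d) {
      loocv_scores(d, classifier = spec)$performance
    })
    tibble::tibble(classifier = spec_name, !!!as.list(perf))
  })
  dplyr::bind_rows(rows)
}
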