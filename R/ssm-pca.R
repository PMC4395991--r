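#' Log-transform an intensity matrix
#'
#' Entrywise natural logarithm; the multiplicative structure of tracer
#' uptake (global scaling per subject, regional modulation) becomes
#' additive, which is what makes the subsequent centering steps meaningful.
#'
#' @param data An `ssm_data_matrix` from [build_data_matrix()], or a plain
#'   numeric matrix of strictly positive intensities.
#' @return Numeric matrix of log intensities.
#' @export
log_transform <- function(data) {
  values <- if (inherits(data, "ssm_data_matrix")) data$values else data
  if (!is.matrix(values)) stop_ssm("`data` must be a matrix or ssm_data_matrix")
  if (any(values <= 0)) {
    stop_ssm("log transform requires strictly positive intensities")
  }
  log(values)
}

#' Doubly center a log-intensity matrix
#'
#' Step 1 removes each subject's own mean over masked voxels (the global
#' scaling factor of that scan); step 2 computes the group mean profile
#' (GMP) as the voxel-wise mean of the row-centered matrix and subtracts
#' it. The result is the subject residual profile (SRP) matrix, whose rows
#' and columns both have zero mean.
#'
#' @param logmat Numeric matrix (subjects x voxels, log units), M >= 2 rows.
#' @return An `ssm_residuals` object: list with `srp` (doubly centered
#'   matrix), `subject_means` (per-row means removed), `gmp` (group mean
#'   profile removed from each column).
#' @export
double_center <- function(logmat) {
  if (!is.matrix(logmat) || nrow(logmat) < 2L) {
    stop_ssm("`logmat` must be a matrix with at least 2 rows")
  }
  subject_means <- rowMeans(logmat)
  centered <- logmat - subject_means
  gmp <- colMeans(centered)
  srp <- sweep(centered, 2L, gmp)
  structure(
    list(srp = srp, subject_means = subject_means, gmp = gmp),
    class = "ssm_residuals"
  )
}

#' Fit the scaled subprofile model (SSM/PCA)
#'
#' Log-transforms and doubly centers the subject-by-voxel matrix, then
#' performs PCA on the subject residual profiles. The eigendecomposition is
#' done in subject space (SRP %*% t(SRP), an M x M problem); each retained
#' component k yields a unit-norm voxel-space pattern, the Group-Invariant
#' Subprofile GIS_k, interpreted as a disease-related metabolic covariance
#' network. The subject score on component k is the projection of that
#' subject's SRP row onto GIS_k; scores are the features handed to the
#' classifiers, columns named `SSPC1..K`.
#'
#' Components with eigenvalue below 1e-10 of the largest are dropped
#' (double centering removes at least one rank, so K <= M - 1). The sign of
#' each pattern is fixed so that its largest-magnitude voxel loading is
#' positive; signs are otherwise arbitrary and must be reproducible for
#' stored models and tree thresholds. Scores are raw projections, never
#' standardized.
#'
#' @param data An `ssm_data_matrix` from [build_data_matrix()] (M >= 3
#'   subjects).
#' @return An `ssm_model`: list with `mask`, `gmp`, `gis` (V x K matrix of
#'   orthonormal patterns), `eigenvalues`, `variance_fraction`, `scores`
#'   (M x K matrix), `subject_ids`, `labels`.
#' @export
fit_ssm <- function(data) {
  if (!inherits(data, "ssm_data_matrix")) {
    stop_ssm("`data` must be an ssm_data_matrix; see build_data_matrix()")
  }
  m <- nrow(data$values)
  if (m < 3L) stop_ssm("need at least 3 subjects to fit the model")
  res <- double_center(log_transform(data))
  cov_s <- tcrossprod(res$srp)            # M x M subject-space covariance
  eig <- eigen(cov_s, symmetric = TRUE)
  lambda <- eig$values
  keep <- which(lambda >= 1e-10 * lambda[1] & lambda > 0)
  lambda <- lambda[keep]
  u <- eig$vectors[, keep, drop = FALSE]
  gis <- crossprod(res$srp, u)            # V x K, columns prop. to patterns
  gis <- sweep(gis, 2L, sqrt(lambda), `/`)  # unit norm
  # reproducible sign: largest-magnitude loading positive
  flip <- vapply(seq_len(ncol(gis)), function(k) {
    j <- which.max(abs(gis[, k]))
    sign(gis[j, k])
  }, numeric(1))
  gis <- sweep(gis, 2L, flip, `*`)
  scores <- res$srp %*% gis
  k <- length(lambda)
  colnames(gis) <- colnames(scores) <- paste0("SSPC", seq_len(k))
  rownames(scores) <- data$subject_ids
  structure(
    list(
      mask = data$mask,
      gmp = res$gmp,
      gis = gis,
      eigenvalues = lambda,
      variance_fraction = lambda / sum(lambda),
      scores = scores,
      subject_ids = data$subject_ids,
      labels = data$labels
    ),
    class = "ssm_model"
  )
}

#' @export
print.ssm_model <- function(x, ...) {
  cat("<ssm_model> ", length(x$subject_ids), " subjects, ",
      nrow(x$gis), " voxels, ", ncol(x$gis), " components\n", sep = "")
  vf <- round(100 * x$variance_fraction[seq_len(min(5, ncol(x$gis)))], 1)
  cat("leading variance fractions (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Project an unseen subject onto a trained model
#'
#' The training mask is reused (no per-subject refit: scores must live in
#' the training feature space). The new subject's masked voxels are
#' log-transformed, their own mean is removed, the training GMP is
#' subtracted, and the residual profile is projected onto each GIS pattern.
#'
#' @param model An `ssm_model` from [fit_ssm()].
#' @param volume A [brain_volume()] congruent with the model's mask grid.
#' @return Named numeric vector of K subject scores (`SSPC1..K`).
#' @export
project_subject <- function(model, volume) {
  vox <- masked_voxels(volume, model$mask)
  if (any(vox <= 0)) {
    stop_ssm("subject '", volume$subject_id,
             "' has non-positive intensity inside the model mask")
  }
  lv <- log(vox)
  srp <- lv - mean(lv) - model$gmp
  drop(crossprod(model$gis, srp))
}

#' Training subject scores as a tibble
#'
#' @param model An `ssm_model`.
#' @return Tibble with `subject_id`, `label`, and score columns `SSPC1..K`.
#' @export
score_table <- function(model) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = model$subject_ids, label = model$labels),
    tibble::as_tibble(model$scores)
  )
}

#' @describeIn fit_ssm One row per retained component: `component`,
#'   `eigenvalue`, `variance_fraction`.
#' @param x,object An `ssm_model`.
#' @param ... Unused.
#' @export
tidy.ssm_model <- function(x, ...) {
  tibble::tibble(
    component = paste0("SSPC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fraction
  )
}

#' @describeIn fit_ssm One-row model summary.
#' @export
glance.ssm_model <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subject_ids),
    n_voxels = nrow(x$gis),
    n_components = ncol(x$gis),
    total_variance = sum(x$eigenvalues)
  )
}

#' @describeIn fit_ssm Variance-accounted-for plot over components.
#' @export
autoplot.ssm_model <- function(object, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = 100 * .data$variance_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "principal component", y = "variance accounted for (%)") +
    ggplot2::theme_minimal()
}

#' Render a GIS pattern as a voxel grid
#'
#' @param model An `ssm_model`.
#' @param component Component index (1-based).
#' @return 3-D array of voxel loadings (0 outside the mask).
#' @export
gis_grid <- function(model, component = 1L) {
  if (component < 1L || component > ncol(model$gis)) {
    stop_ssm("`component` must be in 1..", ncol(model$gis))
  }
  unmask_voxels(model$gis[, component], model$mask)
}

#' Save / load a fitted model
#'
#' Plain-text persistence: the mask, GMP, GIS patterns, eigenvalues and
#' training scores are written as one YAML document, so a stored model can
#' classify future subjects without refitting.
#'
#' @param model An `ssm_model`.
#' @param path File path.
#' @return `path` invisibly; `read_ssm_model()` returns the `ssm_model`.
#' @export
write_ssm_model <- function(model, path) {
  payload <- list(
    mask_dim = dim(model$mask$keep),
    mask_keep = as.integer(model$mask$keep),
    threshold_fraction = model$mask$threshold_fraction,
    gmp = as.numeric(model$gmp),
    gis = lapply(seq_len(ncol(model$gis)), function(k) as.numeric(model$gis[, k])),
    eigenvalues = as.numeric(model$eigenvalues),
    scores = lapply(seq_len(nrow(model$scores)), function(s) as.numeric(model$scores[s, ])),
    subject_ids = model$subject_ids,
    labels = model$labels
  )
  writeLines(yaml::as.yaml(payload, precision = 17L), path)
  invisible(path)
}

#' @rdname write_ssm_model
#' @param path File path.
#' @export
read_ssm_model <- function(path) {
  p <- yaml::read_yaml(path)
  keep <- array(as.logical(p$mask_keep), dim = unlist(p$mask_dim))
  mask <- new_voxel_mask(keep, p$threshold_fraction)
  gis <- do.call(cbind, p$gis)
  scores <- do.call(rbind, p$scores)
  k <- ncol(gis)
  colnames(gis) <- colnames(scores) <- paste0("SSPC", seq_len(k))
  rownames(scores) <- p$subject_ids
  structure(
    list(
      mask = mask,
      gmp = as.numeric(p$gmp),
      gis = gis,
      eigenvalues = as.numeric(p$eigenvalues),
      variance_fraction = as.numeric(p$eigenvalues) / sum(p$eigenvalues),
      scores = scores,
      subject_ids = p$subject_ids,
      labels = p$labels
    ),
    class = "ssm_model"
  )
}
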