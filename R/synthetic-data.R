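#' Spatial pattern with group-dependent expression
#'
#' One embedded covariance pattern: a fixed voxel map whose expression
#' score varies per subject, drawn from a Gaussian whose mean and standard
#' deviation depend on the subject's group. This is the generative premise
#' behind subject scores: each scan contributes to a pattern by an amount
#' that separates (or fails to separate) the groups.
#'
#' @param means Named numeric vector of score means per group label;
#'   groups not named default to 0.
#' @param sd Score standard deviation (scalar, or named per group).
#' @param pattern Optional explicit voxel pattern over the foreground
#'   voxels; `NULL` draws a random one.
#' @return A `pattern_spec`.
#' @export
pattern_spec <- function(means, sd = 1, pattern = NULL) {
  structure(list(means = means, sd = sd, pattern = pattern),
            class = "pattern_spec")
}

#' Synthetic cohort specification
#'
#' Defines a cohort of brain-like volumes: a smooth group mean profile
#' (GMP) on a foreground ("brain") region, a set of mutually orthogonal
#' embedded patterns with group-dependent expression scores, a per-subject
#' global offset, voxel noise, and a near-zero background that the
#' intensity mask removes. Log-intensity of subject s is
#' `gmp + offset_s + sum_k z_sk * pattern_k + noise`, and intensities are
#' its exponential — so the pipeline's log transform is the exact inverse
#' of the generative model.
#'
#' Defaults emulate a four-group parkinsonian cohort (18 HC, 20 PD,
#' 21 MSA, 17 PSP) with one disease-specific pattern per patient group.
#'
#' @param grid_shape Integer triple, default 16 x 16 x 16.
#' @param groups Named integer vector: subjects per group label (>= 2
#'   each).
#' @param patterns List of [pattern_spec()]s; default one pattern per
#'   non-first group with score mean 2.5 in that group, sd 1.
#' @param subject_offset_sd SD (log units) of the per-subject global
#'   offset; removed by row centering downstream.
#' @param noise_sd SD (log units) of i.i.d. voxel noise.
#' @param gmp_profile Optional explicit GMP over foreground voxels; `NULL`
#'   generates a smooth random blob field.
#' @param background_fraction Fraction of grid voxels outside the
#'   foreground, set near zero to exercise masking.
#' @param base_log_intensity Mean log intensity of the foreground.
#' @param gmp_sd SD (log units) of the smooth GMP variation.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(grid_shape = c(16L, 16L, 16L),
                        groups = c(HC = 18L, PD = 20L, MSA = 21L, PSP = 17L),
                        patterns = NULL,
                        subject_offset_sd = 0.1,
                        noise_sd = 0.05,
                        gmp_profile = NULL,
                        background_fraction = 0.4,
                        base_log_intensity = log(100),
                        gmp_sd = 0.1,
                        seed = 1L) {
  if (length(grid_shape) != 3L) stop_ssm("`grid_shape` must be an integer triple")
  if (is.null(names(groups)) || any(groups < 2L)) {
    stop_ssm("`groups` must be a named vector with >= 2 subjects per group")
  }
  if (noise_sd < 0) stop_ssm("`noise_sd` must be >= 0")
  if (is.null(patterns)) {
    patterns <- lapply(names(groups)[-1], function(g) {
      pattern_spec(means = setNames(2.5, g), sd = 1)
    })
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape),
      groups = groups,
      patterns = patterns,
      subject_offset_sd = subject_offset_sd,
      noise_sd = noise_sd,
      gmp_profile = gmp_profile,
      background_fraction = background_fraction,
      base_log_intensity = base_log_intensity,
      gmp_sd = gmp_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Squared distance of every voxel from the grid centre, array layout
# (first index fastest).
centre_dist2 <- function(dims) {
  ax <- lapply(dims, function(d) (seq_len(d) - (d + 1) / 2)^2)
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
}

# Smooth random field over the foreground voxels: a sum of Gaussian blobs
# with random centres and widths, rescaled to the requested sd.
smooth_field <- function(fg_coords, dims, sd_target, n_blobs = 6L) {
  field <- numeric(nrow(fg_coords))
  for (b in seq_len(n_blobs)) {
    centre <- fg_coords[sample.int(nrow(fg_coords), 1L), ]
    width <- stats::runif(1, 0.15, 0.4) * mean(dims)
    d2 <- rowSums(sweep(fg_coords, 2L, centre)^2)
    field <- field + stats::runif(1, -1, 1) * exp(-d2 / (2 * width^2))
  }
  field <- field - mean(field)
  s <- stats::sd(field)
  if (s > 0) field <- field * (sd_target / s)
  field
}

# Mean-remove and orthonormalize pattern columns. Explicitly supplied
# patterns must already be mutually orthogonal after mean removal.
prepare_patterns <- function(spec, n_fg) {
  k <- length(spec$patterns)
  if (k == 0L) return(matrix(numeric(0), nrow = n_fg, ncol = 0L))
  supplied <- !vapply(spec$patterns, function(p) is.null(p$pattern), logical(1))
  raw <- vapply(spec$patterns, function(p) {
    v <- p$pattern %||% rnorm(n_fg)
    if (length(v) != n_fg) {
      stop_ssm("explicit pattern length ", length(v), " != ", n_fg,
               " foreground voxels")
    }
    v - mean(v)
  }, numeric(n_fg))
  raw <- matrix(raw, nrow = n_fg)
  if (any(supplied) && k > 1L) {
    u <- sweep(raw, 2L, sqrt(colSums(raw^2)), `/`)
    g <- crossprod(u)
    if (max(abs(g[upper.tri(g)])) > 1e-8) {
      stop_ssm("supplied patterns are not mutually orthogonal after mean removal")
    }
  }
  q <- qr.Q(qr(raw))                    # orthonormal basis, spans raw
  # keep each column aligned with its source pattern's sign
  al <- sign(colSums(q * raw))
  sweep(q, 2L, ifelse(al == 0, 1, al), `*`)
}

draw_scores <- function(spec) {
  labels <- rep(names(spec$groups), spec$groups)
  k <- length(spec$patterns)
  z <- matrix(0, nrow = length(labels), ncol = k)
  for (j in seq_len(k)) {
    p <- spec$patterns[[j]]
    mu <- rep(0, length(labels))
    for (g in names(p$means)) mu[labels == g] <- p$means[[g]]
    s <- if (length(p$sd) > 1L || !is.null(names(p$sd))) {
      out <- rep(1, length(labels))
      for (g in names(p$sd)) out[labels == g] <- p$sd[[g]]
      out
    } else rep(p$sd, length(labels))
    z[, j] <- rnorm(length(labels), mu, s)
  }
  list(labels = labels, z = z)
}

#' Generate a synthetic cohort of brain-like volumes
#'
#' See [cohort_spec()] for the generative model. Background voxels are set
#' to 1% of the subject's mean foreground intensity, far below the default
#' 35%-of-maximum mask threshold. The returned ground truth (patterns,
#' true scores, GMP, foreground mask) supports recovery assertions: at low
#' noise the fitted leading patterns align with the embedded ones and
#' fitted scores separate the groups as specified.
#'
#' @param spec A [cohort_spec()].
#' @return An `ssm_cohort`: list with `volumes` (list of
#'   [brain_volume()]s), `labels`, and `ground_truth` (list with
#'   `patterns` matrix over foreground voxels, `true_scores` tibble,
#'   `gmp`, `foreground` logical array, `spec`).
#' @export
generate_cohort <- function(spec) {
  withr::with_seed(spec$seed, {
    dims <- spec$grid_shape
    v_total <- prod(dims)
    n_fg <- max(1L, round((1 - spec$background_fraction) * v_total))
    fg_order <- order(as.vector(centre_dist2(dims)))
    fg_idx <- sort(fg_order[seq_len(n_fg)])
    foreground <- array(FALSE, dim = dims)
    foreground[fg_idx] <- TRUE
    fg_coords <- which(foreground, arr.ind = TRUE)

    gmp <- if (!is.null(spec$gmp_profile)) {
      if (length(spec$gmp_profile) != n_fg) {
        stop_ssm("`gmp_profile` length must equal ", n_fg, " foreground voxels")
      }
      spec$gmp_profile
    } else {
      spec$base_log_intensity + smooth_field(fg_coords, dims, spec$gmp_sd)
    }

    patterns <- prepare_patterns(spec, n_fg)
    drawn <- draw_scores(spec)
    labels <- drawn$labels
    ids <- sprintf("%s%02d", labels, stats::ave(seq_along(labels), labels,
                                                FUN = seq_along))
    volumes <- lapply(seq_along(labels), function(s) {
      offset <- rnorm(1, 0, spec$subject_offset_sd)
      eps <- rnorm(n_fg, 0, spec$noise_sd)
      log_fg <- gmp + offset + eps
      if (ncol(patterns) > 0L) {
        log_fg <- log_fg + drop(patterns %*% drawn$z[s, ])
      }
      intens <- exp(log_fg)
      grid <- array(0.01 * mean(intens), dim = dims)
      grid[fg_idx] <- intens
      brain_volume(grid, subject_id = ids[s])
    })

    true_scores <- tibble::tibble(subject_id = ids, label = labels)
    for (j in seq_len(ncol(patterns))) {
      true_scores[[paste0("z", j)]] <- drawn$z[, j]
    }
    structure(
      list(
        volumes = volumes,
        labels = labels,
        ground_truth = list(
          patterns = patterns,
          true_scores = true_scores,
          gmp = gmp,
          foreground = foreground,
          spec = spec
        )
      ),
      class = "ssm_cohort"
    )
  })
}

#' @export
print.ssm_cohort <- function(x, ...) {
  cat("<ssm_cohort> ", length(x$volumes), " volumes (",
      paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)),
            collapse = ", "),
      "), grid ", paste(dim(x$volumes[[1]]$grid), collapse = " x "), "\n",
      sep = "")
  invisible(x)
}

#' Draw a subject-score table directly (no image synthesis)
#'
#' Fast path for classifier and validation tests: draws the per-subject
#' pattern expression scores from the same distributions
#' [generate_cohort()] uses, but skips volume synthesis. Feature columns
#' beyond the embedded patterns are pure standard-normal noise.
#'
#' @param spec A [cohort_spec()].
#' @param n_features Total number of score columns (>= number of
#'   patterns); default the number of patterns.
#' @return Tibble with `subject_id`, `label`, and columns `SSPC1..K`.
#' @export
make_score_table <- function(spec, n_features = NULL) {
  withr::with_seed(spec$seed, {
    drawn <- draw_scores(spec)
    k <- ncol(drawn$z)
    n_features <- n_features %||% max(k, 1L)
    if (n_features < k) stop_ssm("`n_features` must be >= number of patterns")
    m <- length(drawn$labels)
    scores <- cbind(drawn$z, matrix(rnorm(m * (n_features - k)), nrow = m))
    colnames(scores) <- paste0("SSPC", seq_len(n_features))
    ids <- sprintf("%s%02d", drawn$labels,
                   stats::ave(seq_along(drawn$labels), drawn$labels, FUN = seq_along))
    dplyr::bind_cols(
      tibble::tibble(subject_id = ids, label = drawn$labels),
      tibble::as_tibble(scores)
    )
  })
}

#' Write a cohort's ground truth as delimited text
#'
#' @param cohort An `ssm_cohort`.
#' @param dir Output directory (created if needed): writes
#'   `true_scores.csv` and `patterns.csv` (foreground voxel index +
#'   pattern loadings).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$ground_truth$true_scores,
                   file.path(dir, "true_scores.csv"), row.names = FALSE)
  pats <- cohort$ground_truth$patterns
  df <- data.frame(voxel = which(cohort$ground_truth$foreground))
  for (j in seq_len(ncol(pats))) df[[paste0("pattern", j)]] <- pats[, j]
  utils::write.csv(df, file.path(dir, "patterns.csv"), row.names = FALSE)
  invisible(dir)
}
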