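# Shared fixtures and independent oracles.

# Small two-group cohort with one strongly expressed pattern.
small_cohort <- function(seed = 1L, n = 6L, grid = c(8L, 8L, 8L),
                         sep = 2, sd = 0.5, noise_sd = 0.05) {
  cohort_spec(
    grid_shape = grid,
    groups = c(HC = n, PD = n),
    patterns = list(pattern_spec(means = c(HC = -sep, PD = sep), sd = sd)),
    noise_sd = noise_sd,
    seed = seed
  )
}

# Correlation between a fitted voxel pattern and an embedded ground-truth
# pattern, on the voxels common to the model mask and the foreground.
pattern_recovery_cor <- function(model, cohort, component = 1L, pattern = 1L) {
  fg_idx <- which(cohort$ground_truth$foreground)
  mask_idx <- which(model$mask$keep)
  common <- intersect(fg_idx, mask_idx)
  stats::cor(
    cohort$ground_truth$patterns[match(common, fg_idx), pattern],
    model$gis[match(common, mask_idx), component]
  )
}

# Brute-force split search: plain enumeration over every midpoint between
# consecutive distinct sorted values, written independently of best_split().
oracle_best_split <- function(values, labels, min_cases) {
  shannon <- function(l) {
    p <- as.vector(table(l)) / length(l)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  sv <- sort(unique(values))
  if (length(sv) < 2L) return(NULL)
  rows <- NULL
  n <- length(values)
  for (i in seq_len(length(sv) - 1L)) {
    mid <- (sv[i] + sv[i + 1L]) / 2
    nl <- sum(values <= mid)
    nr <- n - nl
    if (nl < min_cases || nr < min_cases) next
    gain <- shannon(labels) -
      (nl * shannon(labels[values <= mid]) + nr * shannon(labels[values > mid])) / n
    si <- shannon(c(rep("l", nl), rep("r", nr)))
    rows <- rbind(rows, c(mid = mid, gain = gain, ratio = gain / si))
  }
  if (is.null(rows)) return(NULL)
  rows <- rows[rows[, "gain"] >= mean(rows[, "gain"]) - 1e-12, , drop = FALSE]
  # same documented tie rule as the implementation: near-equal ratios
  # resolve to the smallest threshold
  best <- rows[which(rows[, "ratio"] >= max(rows[, "ratio"]) - 1e-12)[1], ]
  list(
    threshold = max(values[values <= best[["mid"]]]),
    gain = best[["gain"]],
    gain_ratio = best[["ratio"]]
  )
}

# Upper binomial confidence bound by direct root finding: the error rate p
# at which observing at most e errors in n cases has probability cf
# (independent of the qbeta-based implementation).
oracle_error_ubound <- function(e, n, cf) {
  if (e >= n) return(1)
  f <- function(p) stats::pbinom(e, n, p) - cf
  u <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  max(u, e / n)
}
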