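test_that("log transform is the entrywise natural log with domain check", {
  expect_equal(log_transform(matrix(c(1, exp(1)), 1)), matrix(c(0, 1), 1))
  expect_error(log_transform(matrix(c(1, 0), 1)), "strictly positive")
})

test_that("double centering matches hand arithmetic and annihilates constants", {
  out <- double_center(matrix(c(0, 1, 2, 5), nrow = 2))
  expect_equal(unname(out$subject_means), c(1, 3))
  expect_equal(unname(out$gmp), c(-1.5, 1.5))
  expect_equal(unname(out$srp), matrix(c(0.5, -0.5, -0.5, 0.5), nrow = 2))

  const <- double_center(matrix(7, nrow = 3, ncol = 4))
  expect_true(all(const$srp == 0))
  expect_true(all(const$gmp == 0))
})

test_that("doubly centered rows and columns have zero mean", {
  set.seed(21)
  for (i in 1:5) {
    srp <- double_center(matrix(rnorm(10 * 200), nrow = 10))$srp
    expect_lt(max(abs(rowMeans(srp))), 1e-10)
    expect_lt(max(abs(colMeans(srp))), 1e-10)
  }
})

random_data_matrix <- function(m, v, seed) {
  set.seed(seed)
  vals <- matrix(exp(rnorm(m * v, 0, 0.3)), nrow = m)
  rownames(vals) <- paste0("s", seq_len(m))
  structure(
    list(
      values = vals,
      subject_ids = rownames(vals),
      labels = rep(c("a", "b"), length.out = m),
      mask = ssmtree:::new_voxel_mask(array(TRUE, dim = c(v, 1, 1)))
    ),
    class = "ssm_data_matrix"
  )
}

test_that("fit_ssm matches an independent SVD decomposition", {
  dm <- random_data_matrix(5, 50, seed = 31)
  model <- fit_ssm(dm)
  srp <- double_center(log(dm$values))$srp
  sv <- svd(srp)
  k <- ncol(model$gis)
  expect_equal(model$eigenvalues, sv$d[seq_len(k)]^2, tolerance = 1e-8)
  # scores and patterns agree up to the documented sign convention
  for (j in seq_len(k)) {
    ref <- sv$u[, j] * sv$d[j]
    expect_equal(abs(unname(model$scores[, j])), abs(ref), tolerance = 1e-8)
    expect_equal(abs(model$gis[, j]), abs(sv$v[, j]), tolerance = 1e-8)
  }
})

test_that("fitted model satisfies its structural invariants", {
  dm <- random_data_matrix(8, 100, seed = 32)
  model <- fit_ssm(dm)
  srp <- double_center(log(dm$values))$srp
  k <- ncol(model$gis)
  expect_lte(k, 7L)                                 # double centering drops rank
  gram <- crossprod(model$gis)
  expect_equal(gram, diag(k), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(model$eigenvalues) <= 1e-10))
  expect_equal(sum(model$eigenvalues), sum(srp^2), tolerance = 1e-8)
  expect_equal(sum(model$variance_fraction), 1, tolerance = 1e-10)
  expect_equal(unname(srp %*% model$gis), unname(model$scores), tolerance = 1e-8)
  expect_error(fit_ssm(random_data_matrix(2, 10, 1)), "at least 3")
})

test_that("fit is invariant under subject permutation; dropping one subject moves scores", {
  dm <- random_data_matrix(7, 60, seed = 33)
  model <- fit_ssm(dm)
  perm <- c(4, 2, 7, 1, 3, 6, 5)
  dmp <- dm
  dmp$values <- dm$values[perm, ]
  dmp$subject_ids <- dm$subject_ids[perm]
  dmp$labels <- dm$labels[perm]
  modelp <- fit_ssm(dmp)
  expect_equal(abs(unname(modelp$scores)), abs(unname(model$scores[perm, ])),
               tolerance = 1e-8)

  # removing a subject perturbs every remaining score: features depend on
  # the whole dataset, which is why validation refits per fold
  dm1 <- dm
  dm1$values <- dm$values[-1, ]
  dm1$subject_ids <- dm$subject_ids[-1]
  dm1$labels <- dm$labels[-1]
  model1 <- fit_ssm(dm1)
  expect_true(all(abs(abs(model1$scores[, 1]) - abs(model$scores[-1, 1])) > 1e-8))
})

test_that("projection reproduces training scores and recovers constructions", {
  co <- generate_cohort(small_cohort(seed = 41, n = 5))
  dm <- build_data_matrix(co$volumes, co$labels)
  model <- fit_ssm(dm)

  for (i in c(1, 4, 9)) {
    expect_equal(project_subject(model, co$volumes[[i]]),
                 model$scores[i, ], tolerance = 1e-8)
  }

  dims <- dim(model$mask$keep)
  # log profile equal to gmp plus a constant projects to all-zero scores
  flat <- exp(model$gmp + 0.7)
  v0 <- brain_volume(unmask_voxels(flat, model$mask, fill = 1), "flat")
  expect_lt(max(abs(project_subject(model, v0))), 1e-8)

  # gmp plus 2.5 times the first pattern scores (2.5, 0, ..., 0)
  g1 <- model$gis[, 1]
  v1 <- brain_volume(unmask_voxels(exp(model$gmp + 2.5 * g1), model$mask, fill = 1),
                     "constructed")
  sc <- project_subject(model, v1)
  expect_equal(unname(sc[1]), 2.5, tolerance = 1e-6)
  expect_lt(max(abs(sc[-1])), 1e-6)

  bad <- co$volumes[[2]]
  bad$grid[which(model$mask$keep)[1]] <- 0
  expect_error(project_subject(model, bad), "non-positive")
})

test_that("low-noise cohorts recover the embedded pattern", {
  spec <- small_cohort(seed = 43, n = 8, noise_sd = 0.02)
  co <- generate_cohort(spec)
  model <- fit_ssm(build_data_matrix(co$volumes, co$labels))
  expect_gte(abs(pattern_recovery_cor(model, co)), 0.9)
  # leading scores separate the groups
  s1 <- model$scores[, 1]
  hc <- s1[co$labels == "HC"]; pd <- s1[co$labels == "PD"]
  expect_true(max(hc) < min(pd) || max(pd) < min(hc))
})

test_that("models persist to plain text and back", {
  co <- generate_cohort(small_cohort(seed = 47, n = 4))
  model <- fit_ssm(build_data_matrix(co$volumes, co$labels))
  path <- tempfile(fileext = ".yaml")
  write_ssm_model(model, path)
  back <- read_ssm_model(path)
  expect_equal(back$gis, model$gis)
  expect_equal(back$scores, model$scores)
  expect_equal(back$mask$keep, model$mask$keep)
  expect_equal(project_subject(back, co$volumes[[3]]),
               project_subject(model, co$volumes[[3]]))
})

test_that("score_table and tidiers expose the model as tibbles", {
  co <- generate_cohort(small_cohort(seed = 49, n = 4))
  model <- fit_ssm(build_data_matrix(co$volumes, co$labels))
  st <- score_table(model)
  expect_s3_class(st, "tbl_df")
  expect_named(st, c("subject_id", "label", paste0("SSPC", seq_along(model$eigenvalues))))
  td <- tidy(model)
  expect_equal(nrow(td), length(model$eigenvalues))
  expect_equal(glance(model)$n_subjects, 8L)
  expect_s3_class(autoplot(model), "ggplot")
})
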