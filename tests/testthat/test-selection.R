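make_fm <- function(X) {
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  rownames(X) <- sprintf("r%03d", seq_len(nrow(X)))
  feature_matrix(X, "descriptor",
                 setNames(rep("synthetic", ncol(X)), colnames(X)))
}

test_that("prefilter applies the three rules in order", {
  set.seed(1)
  n <- 100
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  X <- cbind(X,
             const = rep(3.7, n),                   # rule 1
             nearid = c(rep(5, 96), rnorm(4)),      # rule 2 (96% identical)
             dup = X[, 1])                          # rule 3 (r = 1)
  fm <- make_fm(X)
  out <- prefilter(fm, seed = 11)
  rep <- out$report
  expect_true("f04" %in% rep$removed_zero_variance)
  expect_true("f05" %in% rep$removed_high_identity)
  expect_equal(nrow(rep$removed_correlated), 1)
  expect_setequal(c(rep$removed_correlated$removed,
                    rep$removed_correlated$kept), c("f01", "f06"))
  expect_true(abs(rep$removed_correlated$r) > 0.95)
  # partition of input columns
  expect_setequal(c(rep$removed_zero_variance, rep$removed_high_identity,
                    rep$removed_correlated$removed, rep$surviving),
                  colnames(fm))
  # idempotence: second pass removes nothing
  out2 <- prefilter(out$matrix, seed = 11)
  expect_identical(colnames(out2$matrix), colnames(out$matrix))
  # everything removed is an error
  expect_error(prefilter(make_fm(matrix(1, 10, 3))), "no informative")
})

test_that("RFE follows the step-2 schedule with nested feature sets", {
  gen <- fixture_dataset("regression", n = 60, p = 10, informative = 3)
  path <- rf_rfe(gen$dataset, cv_folds = 3, estimators = 100, seed = 2)
  sizes <- vapply(path$steps, `[[`, numeric(1), "n_features")
  expect_equal(sizes, c(10, 8, 6, 4, 2))
  for (i in seq_len(length(path$steps) - 1))
    expect_true(all(path$steps[[i + 1]]$features %in%
                      path$steps[[i]]$features))
  # reproducibility end to end
  path2 <- rf_rfe(gen$dataset, cv_folds = 3, estimators = 100, seed = 2)
  expect_equal(vapply(path2$steps, `[[`, numeric(1), "cv_score"),
               vapply(path$steps, `[[`, numeric(1), "cv_score"))
})

test_that("select_best maximizes the CV score with ties toward fewer features", {
  fake <- structure(list(steps = list(
    list(n_features = 6, features = letters[1:6], cv_score = 0.5),
    list(n_features = 4, features = letters[1:4], cv_score = 0.9),
    list(n_features = 2, features = letters[1:2], cv_score = 0.7)),
    best_index = 2L), class = "rfe_path")
  expect_equal(select_best(fake), letters[1:4])
  tie <- structure(list(steps = list(
    list(n_features = 6, features = letters[1:6], cv_score = 0.9),
    list(n_features = 4, features = letters[1:4], cv_score = 0.9)),
    best_index = 2L), class = "rfe_path")
  expect_equal(select_best(tie), letters[1:4])
})

test_that("RFE on pure noise does not invent signal", {
  scores <- vapply(1:3, function(s) {
    gen <- generate_qsar_dataset(synthetic_spec(
      80, "regression", n_features = 12, n_informative = 0,
      effect_sizes = numeric(0), noise_sigma = 1, seed = 50 + s))
    path <- rf_rfe(gen$dataset, cv_folds = 3, estimators = 100,
                   seed = 50 + s)
    max(vapply(path$steps, `[[`, numeric(1), "cv_score"))
  }, numeric(1))
  expect_lt(mean(scores), 0.2)
})
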