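# Independent brute-force oracles for every metric.
oracle_r2 <- function(y, yhat, ybar) {
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    num <- num + (yhat[i] - y[i])^2
    den <- den + (y[i] - ybar)^2
  }
  1 - num / den
}
oracle_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}
oracle_kappa <- function(y, l) {
  n <- length(y)
  po <- sum(y == l) / n
  pe <- (sum(y == 1) / n) * (sum(l == 1) / n) +
    (sum(y == 0) / n) * (sum(l == 0) / n)
  (po - pe) / (1 - pe)
}

test_that("regression metrics match hand arithmetic and the formula edge cases", {
  out <- regression_metrics(c(1, 2, 3), c(1, 2, 4), ybar_reference = 2)
  expect_equal(out$RMSE, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(out$R2, 0.5, tolerance = 1e-12)
  y <- rnorm(10)
  exact <- regression_metrics(y, y)
  expect_equal(exact$R2, 1)
  expect_equal(exact$RMSE, 0)
  # predicting the mean gives R2 = 0
  expect_equal(regression_metrics(y, rep(mean(y), 10))$R2, 0)
  expect_error(regression_metrics(rep(2, 5), rnorm(5)), "undefined")
})

test_that("classification metrics reproduce the confusion-count identities", {
  # TP=8 TN=6 FP=2 FN=4
  y <- c(rep(1, 12), rep(0, 8))
  s <- c(rep(0.9, 8), rep(0.1, 4), rep(0.8, 2), rep(0.2, 6))
  m <- classification_metrics(y, s)
  expect_equal(unname(m$counts), c(8, 2, 6, 4))
  expect_equal(m$ACC, 0.70)
  expect_equal(m$SE, 8 / 12)
  expect_equal(m$SP, 0.75)
  # perfectly separated scores
  expect_equal(classification_metrics(c(0, 0, 1, 1),
                                      c(0.1, 0.2, 0.8, 0.9))$AUC, 1)
  expect_error(classification_metrics(c(1, 1), c(0.2, 0.8)), "single class")
})

test_that("kappa matches hand arithmetic and its fixed points", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_equal(cohens_kappa(y, y), 1)
  # contingency (a,b,c,d) = (20,5,10,15): po=0.7, pe=0.5 -> kappa 0.4
  yt <- c(rep(1, 25), rep(0, 25))
  yp <- c(rep(1, 20), rep(0, 5), rep(1, 10), rep(0, 15))
  expect_equal(cohens_kappa(yt, yp), (0.7 - 0.5) / 0.5, tolerance = 1e-12)
  expect_warning(k <- cohens_kappa(rep(1, 5), rep(1, 5)), "kappa")
  expect_equal(k, 0)
})

test_that("all metrics agree with brute-force oracles on random instances", {
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(5:100, 1)
    y <- rnorm(n); yhat <- y + rnorm(n); ybar <- mean(y) + runif(1, -1, 1)
    m <- regression_metrics(y, yhat, ybar)
    expect_equal(m$R2, oracle_r2(y, yhat, ybar), tolerance = 1e-10)
    expect_equal(m$RMSE, oracle_rmse(y, yhat), tolerance = 1e-10)

    yb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # rounding forces ties
    cm <- classification_metrics(yb, s)
    expect_equal(cm$AUC, oracle_auc(yb, s), tolerance = 1e-10)
    labs <- as.integer(s >= 0.5)
    if (abs(1 - ((mean(yb) * mean(labs)) +
                 (1 - mean(yb)) * (1 - mean(labs)))) > 1e-12)
      expect_equal(cm$kappa, oracle_kappa(yb, labs), tolerance = 1e-10)
    expect_equal(cm$ACC, mean(yb == labs), tolerance = 1e-12)
  }
})

test_that("fold-error formula and rates behave as printed", {
  expect_equal(fold_error_rates(10, 15)$folds, 1.5)
  expect_equal(fold_error_rates(10, 25)$folds, 2.5)
  fe <- fold_error_rates(c(10, 10), c(15, 25))
  expect_equal(unname(fe$within), c(0.5, 1.0))
  expect_equal(fe$average_fold, 2.0)
  perfect <- fold_error_rates(c(1, 5, 9), c(1, 5, 9))
  expect_equal(perfect$average_fold, 1.0)
  expect_equal(unname(perfect$within), c(1, 1))
  expect_error(fold_error_rates(c(0, 1), c(1, 1)), "zero truth")
  expect_error(fold_error_rates(c(-1, 1), c(1, 1)), "positive")
  # within_2fold is monotone nonincreasing in a growing error factor
  y <- runif(20, 1, 10)
  rates <- vapply(c(1, 1.5, 2, 3, 5), function(f)
    fold_error_rates(y, y * f)$within[["within_2fold"]], numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("cross-validation builds balanced folds and matches a manual loop", {
  gen <- fixture_dataset("regression", n = 10, p = 4, informative = 2)
  cfg <- model_config("rf", "regression", list(estimators = 100L), seed = 5)
  # fold sizes differ by <= 1
  cv <- cross_validate(gen$dataset, cfg, k = 4, seed = 3)
  expect_true(is.finite(cv$Q2))
  # leave-one-out equals a brute-force loop with the same per-fold fits
  loo <- cross_validate(gen$dataset, cfg, k = 10, seed = 3)
  X <- unclass(gen$dataset$features); y <- gen$dataset$y
  set.seed(3)
  fold <- integer(10); fold[sample.int(10)] <- rep(1:10, length.out = 10)
  oof <- numeric(10)
  for (f in 1:10) {
    tr <- fold != f
    sub <- labeled_dataset(
      feature_matrix(X[tr, , drop = FALSE], "descriptor",
                     attr(gen$dataset$features, "family")),
      y[tr], task = "regression")
    oof[!tr] <- predict(train(sub, cfg), X[!tr, , drop = FALSE])
  }
  expect_equal(loo$oof, oof)
  expect_equal(loo$Q2, 1 - sum((oof - y)^2) / sum((y - mean(y))^2))
  expect_error(cross_validate(gen$dataset, cfg, k = 11), "exceed")
})

test_that("stratified CV preserves per-fold class balance", {
  gen <- fixture_dataset("classification", n = 100, p = 4, informative = 2,
                         balance = 0.2, seed = 77)
  cfg <- model_config("rf", "classification", list(estimators = 50L),
                      seed = 1)
  # stratified folds each hold 20 compounds with 4 positives
  X <- unclass(gen$dataset$features); y <- gen$dataset$y
  set.seed(9)
  fold <- integer(100)
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep(1:5,
                                              length.out = length(idx))
  }
  expect_true(all(tapply(y, fold, sum) == 4))
  out <- cross_validate(gen$dataset, cfg, k = 5, seed = 9,
                        stratify = TRUE)
  expect_true(is.finite(out$AUC))
})

test_that("out-of-fold error is no better than fit error on average", {
  diffs <- vapply(1:10, function(s) {
    gen <- generate_qsar_dataset(synthetic_spec(
      50, "regression", n_features = 5, n_informative = 2,
      noise_sigma = 1, seed = 300 + s))
    cfg <- model_config("rf", "regression", list(estimators = 100L),
                        seed = s)
    m <- train(gen$dataset, cfg)
    fit <- regression_metrics(gen$dataset$y,
                              predict(m, gen$dataset$features))$R2
    cv <- cross_validate(gen$dataset, cfg, k = 5, seed = s)$Q2
    fit - cv
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("test-set R2 uses the training-set mean by contract", {
  y_test <- c(1, 2, 3)
  pred <- c(1.1, 2.1, 2.9)
  ybar_train <- 10
  m <- regression_metrics(y_test, pred, ybar_reference = ybar_train,
                          context = "test")
  expect_equal(m$R2, 1 - sum((pred - y_test)^2) /
                 sum((y_test - ybar_train)^2), tolerance = 1e-12)
})
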