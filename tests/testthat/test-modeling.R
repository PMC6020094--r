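test_that("algorithm/task compatibility is enforced", {
  expect_error(model_config("naive_bayes", "regression"), "not available")
  expect_error(model_config("pls", "classification"), "not available")
  expect_s3_class(model_config("rf", "regression"), "model_config")
  gen <- fixture_dataset("regression")
  cfg <- model_config("rf", "classification")
  expect_error(train(gen$dataset, cfg), "does not match")
})

test_that("grid schedules reproduce the canonical ladders exactly", {
  expect_equal(rf_stage1_mtry_grid(100), c(1, 21, 41, 61, 81))
  expect_equal(rf_stage1_mtry_grid(15), c(1))
  expect_equal(rf_stage2_mtry_grid(61, 200), seq(11, 111, by = 2))
  expect_equal(rf_stage2_mtry_grid(10, 40), seq(2, 40, by = 2))
  expect_equal(svm_stage1_C_exponents(), seq(-5, 15, by = 2))
  expect_length(svm_stage1_C_exponents(), 11)
  expect_equal(svm_stage1_sigma_exponents(), seq(-15, 3, by = 2))
  expect_length(svm_stage1_sigma_exponents(), 10)
  expect_equal(svm_stage2_exponents(3), seq(1, 5, by = 0.25))
  expect_equal(pls_component_grid(5, 50), 1:5)
  expect_equal(pls_component_grid(300, 300), 1:100)
  expect_equal(pls_component_grid(300, 30), 1:28)
})

test_that("training is deterministic and separable data fits exactly", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  colnames(X) <- c("f1", "f2"); rownames(X) <- paste0("r", 1:40)
  fm <- feature_matrix(X, "descriptor", c(f1 = "syn", f2 = "syn"))
  ds <- labeled_dataset(fm, rep(c(0, 1), each = 20),
                        task = "classification")
  m <- train(ds, model_config("rf", "classification", seed = 4))
  expect_equal(predict(m, fm)$label, ds$y)
  m2 <- train(ds, model_config("rf", "classification", seed = 4))
  expect_identical(predict(m, fm)$probability,
                   predict(m2, fm)$probability)
})

test_that("predict validates feature names", {
  gen <- fixture_dataset("regression")
  m <- train(gen$dataset, model_config("rf", "regression", seed = 1))
  X <- unclass(gen$dataset$features)
  colnames(X)[1] <- "wrong_name"
  expect_error(predict(m, X), "feature mismatch")
})

test_that("grid searches return bests inside their grids", {
  gen <- fixture_dataset("regression", n = 50, p = 6, informative = 2)
  gr <- grid_search_rf(gen$dataset, cv_folds = 3, seed = 1)
  expect_true(gr$final_best$mtry %in% gr$stage2_grid$mtry)
  expect_true(gr$final_best$estimators %in% c(500, 1000))
  gp <- grid_search_pls(gen$dataset, cv_folds = 3, seed = 1)
  expect_true(gp$final_best$n_components %in% gp$stage1_grid)
})

test_that("balanced RF grows every tree on samplesize compounds per class", {
  gen <- fixture_dataset("classification", n = 300, p = 6,
                         informative = 3, balance = 0.2, seed = 9)
  m <- train_balanced_rf(gen$dataset, samplesize = 30, estimators = 150,
                         seed = 1)
  inbag <- m$extra$inbag
  y <- m$extra$y
  pos_counts <- colSums(inbag[y == 1, , drop = FALSE] > 0)
  neg_counts <- colSums(inbag[y == 0, , drop = FALSE] > 0)
  expect_true(all(pos_counts == 30))
  expect_true(all(neg_counts == 30))
  # samplesize above the minority class is an error without replacement
  expect_error(train_balanced_rf(gen$dataset, samplesize = 1000),
               "without replacement")
})

test_that("consensus aggregates member probabilities as their mean", {
  gen <- fixture_dataset("classification", n = 200, p = 6,
                         informative = 3, balance = 0.2, seed = 10)
  cm <- train_resampling_consensus(gen$dataset, n_members = 10, seed = 3)
  expect_length(cm$members, 10)
  probe <- gen$dataset$features
  member_probs <- vapply(cm$members, function(m)
    predict(m, probe)$probability, numeric(nrow(probe)))
  expect_equal(predict(cm, probe)$probability, rowMeans(member_probs))
  # each member trains on 2 * minority compounds
  expect_equal(cm$members[[1]]$training_summary$n,
               2 * sum(gen$dataset$y == 1))
  # near-balanced input warns
  bal <- fixture_dataset("classification", n = 100, p = 4,
                         informative = 2, balance = 0.5, seed = 2)
  expect_warning(train_resampling_consensus(bal$dataset, n_members = 2,
                                            seed = 1), "balanced")
})

test_that("imbalance strategies shrink the SE-SP gap versus standard RF", {
  gaps <- sapply(1:3, function(s) {
    gen <- generate_qsar_dataset(synthetic_spec(
      600, "classification", n_features = 10, n_informative = 5,
      class_balance = 0.1, seed = 200 + s))
    ds <- gen$dataset
    set.seed(s); tr <- sample(600, 400)
    part <- function(ix) labeled_dataset(
      feature_matrix(unclass(ds$features)[ix, , drop = FALSE],
                     "descriptor", attr(ds$features, "family")),
      ds$y[ix], task = "classification")
    trn <- part(tr); tst <- part(setdiff(seq_len(600), tr))
    gap <- function(model) {
      cmx <- classification_metrics(
        tst$y, predict(model, tst$features)$probability)
      abs(cmx$SE - cmx$SP)
    }
    c(std = gap(train(trn, model_config("rf", "classification",
                                        list(estimators = 300L),
                                        seed = s))),
      bal = gap(train_balanced_rf(trn, estimators = 300, seed = s)),
      con = gap(train_resampling_consensus(trn, seed = s)))
  })
  means <- rowMeans(gaps)
  expect_lt(means[["bal"]], means[["std"]])
  expect_lt(means[["con"]], means[["std"]])
})
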