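# The evaluation suite: R2/RMSE triplets for regression (fit, CV, test),
# ACC/SP/SE/AUC and Cohen's kappa for classification, and the fold-error
# rates used for pharmacokinetic endpoints.

#' Regression metrics
#'
#' `R2 = 1 - sum((yhat - y)^2) / sum((y - ybar)^2)` and
#' `RMSE = sqrt(mean((y - yhat)^2))`. The reference mean `ybar` is always
#' the training-set mean, including for test-set R2: this is a deliberate
#' contract, so test R2 measures improvement over predicting the training
#' mean.
#'
#' @param y_true Observed values.
#' @param y_pred Predicted values.
#' @param ybar_reference Training-set mean of the endpoint. Defaults to
#'   `mean(y_true)` (the fitting context).
#' @param context One of `"fit"`, `"cv"`, `"test"`; labels the result.
#' @return List with `R2`, `RMSE`, `context`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4), ybar_reference = 2)
#' @export
regression_metrics <- function(y_true, y_pred,
                               ybar_reference = mean(y_true),
                               context = c("fit", "cv", "test")) {
  context <- match.arg(context)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  denom <- sum((y_true - ybar_reference)^2)
  if (denom == 0)
    stop("R2 undefined: all observed values equal the reference mean")
  list(R2 = 1 - sum((y_pred - y_true)^2) / denom,
       RMSE = sqrt(mean((y_true - y_pred)^2)),
       context = context)
}

#' Classification metrics
#'
#' Thresholds scores into labels, builds the confusion counts, and computes
#' `ACC`, `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, rank-statistic `AUC` (ties
#' contribute 1/2) and Cohen's kappa.
#'
#' @param y_true Binary 0/1 truth.
#' @param scores Predicted scores/probabilities in `[0, 1]`.
#' @param threshold Label threshold (default 0.5).
#' @return List with `ACC`, `SP`, `SE`, `AUC`, `kappa` and `counts`
#'   (TP/FP/TN/FN). With single-class truth SE or SP is `NA` and AUC is an
#'   error.
#' @export
classification_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  labels <- as.integer(scores >= threshold)
  TP <- sum(labels == 1 & y_true == 1)
  FP <- sum(labels == 1 & y_true == 0)
  TN <- sum(labels == 0 & y_true == 0)
  FN <- sum(labels == 0 & y_true == 1)
  n_pos <- TP + FN; n_neg <- TN + FP
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: y_true contains a single class")
  r <- rank(scores)
  auc <- (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(ACC = (TP + TN) / length(y_true),
       SP = TN / n_neg, SE = TP / n_pos, AUC = auc,
       kappa = cohens_kappa(y_true, labels),
       counts = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' Cohen's kappa
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the chance agreement `p_e` from
#' the marginal products. When both label vectors are constant and equal
#' (`p_e = 1`), kappa is defined as 0 with a warning.
#'
#' @param y_true,y_pred_labels Binary 0/1 label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(y_true, y_pred_labels) {
  stopifnot(length(y_true) == length(y_pred_labels),
            all(y_true %in% c(0, 1)), all(y_pred_labels %in% c(0, 1)))
  n <- length(y_true)
  po <- mean(y_true == y_pred_labels)
  pe <- mean(y_true == 1) * mean(y_pred_labels == 1) +
    mean(y_true == 0) * mean(y_pred_labels == 0)
  if (abs(1 - pe) < 1e-15) {
    warning("both label vectors constant and equal; kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Fold-error rates
#'
#' Per-sample fold error `fold = 1 + |y_pred - y_true| / y_true` and the
#' fractions predicted within each fold threshold. A method with an
#' average fold below 2 is conventionally considered successful.
#'
#' @param y_true Strictly positive observed values.
#' @param y_pred Predictions.
#' @param thresholds Fold thresholds (default `c(2, 3)`).
#' @return List with `folds` (per-sample), `within` (named fractions, e.g.
#'   `within_2fold`), and `average_fold`.
#' @examples
#' fold_error_rates(10, 15)$folds  # 1.5
#' @export
fold_error_rates <- function(y_true, y_pred, thresholds = c(2, 3)) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(y_true == 0)) stop("fold error undefined at zero truth")
  if (any(y_true < 0)) stop("fold error requires positive observed values")
  folds <- 1 + abs(y_pred - y_true) / y_true
  within <- vapply(thresholds, function(t) mean(folds <= t), numeric(1))
  names(within) <- paste0("within_", thresholds, "fold")
  list(folds = folds, within = within, average_fold = mean(folds))
}

#' k-fold cross-validation of a model configuration
#'
#' Splits the dataset into `k` roughly equal parts (shuffled indices under
#' `seed`, assigned round-robin; fold sizes differ by at most one), holds
#' each part out once, and pools the out-of-fold predictions. Regression
#' returns Q2 (against the full training-set mean) and RMSE_cv;
#' classification returns the pooled [classification_metrics()].
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [model_config()].
#' @param k Number of folds (default 5); `k = n` gives leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @param stratify Deal each class round-robin separately so per-fold
#'   class balance is preserved (classification only; default off).
#' @return Regression: list with `Q2`, `RMSE_cv`, `oof`. Classification:
#'   [classification_metrics()] output plus `oof`.
#' @export
cross_validate <- function(dataset, config, k = 5L, seed = 1L,
                           stratify = FALSE) {
  n <- nrow(dataset$features)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k must not exceed the number of compounds")
  X <- unclass(dataset$features)
  y <- dataset$y
  set.seed(seed)
  fold <- integer(n)
  if (stratify && dataset$task == "classification") {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <-
        rep(seq_len(k), length.out = length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  }
  oof <- numeric(n)
  clf <- dataset$task == "classification"
  for (f in seq_len(k)) {
    tr <- fold != f
    sub <- labeled_dataset(
      feature_matrix(X[tr, , drop = FALSE], attr(dataset$features, "kind"),
                     attr(dataset$features, "family")),
      y[tr], dataset$endpoint, dataset$task)
    m <- train(sub, config)
    pr <- predict(m, X[!tr, , drop = FALSE])
    oof[!tr] <- if (clf) pr$probability else pr
  }
  if (clf) {
    out <- classification_metrics(y, oof)
    out$oof <- oof
    out
  } else {
    mets <- regression_metrics(y, oof, ybar_reference = mean(y),
                               context = "cv")
    list(Q2 = mets$R2, RMSE_cv = mets$RMSE, oof = oof)
  }
}

#' Full evaluation report for a fitted configuration
#'
#' Convenience wrapper producing the complete metric set: for regression
#' R2_F/RMSE_F (fit), Q2/RMSE_cv (cross-validation) and, when a test set is
#' supplied, R2_T/RMSE_T computed against the training-set mean; for
#' classification the pooled CV metrics and test-set metrics.
#'
#' @param train_set,test_set [labeled_dataset()]s (`test_set` optional).
#' @param config A [model_config()].
#' @param k CV folds.
#' @param seed Integer seed.
#' @param fold_errors Also compute [fold_error_rates()] (regression with
#'   strictly positive endpoint values).
#' @return Named list of metrics (an `eval_report`).
#' @export
evaluate_model <- function(train_set, config, test_set = NULL, k = 5L,
                           seed = 1L, fold_errors = FALSE) {
  model <- train(train_set, config)
  ybar <- mean(train_set$y)
  out <- list()
  if (train_set$task == "regression") {
    fit_pred <- predict(model, train_set$features)
    fit <- regression_metrics(train_set$y, fit_pred, ybar, "fit")
    cv <- cross_validate(train_set, config, k, seed)
    out$R2_F <- fit$R2; out$RMSE_F <- fit$RMSE
    out$Q2 <- cv$Q2; out$RMSE_cv <- cv$RMSE_cv
    if (fold_errors) {
      fe <- fold_error_rates(train_set$y, cv$oof)
      out$within_2fold_cv <- fe$within[["within_2fold"]]
      out$within_3fold_cv <- fe$within[["within_3fold"]]
      out$average_fold_cv <- fe$average_fold
    }
    if (!is.null(test_set)) {
      tp <- predict(model, test_set$features)
      tst <- regression_metrics(test_set$y, tp, ybar, "test")
      out$R2_T <- tst$R2; out$RMSE_T <- tst$RMSE
      if (fold_errors) {
        fe <- fold_error_rates(test_set$y, tp)
        out$within_2fold_test <- fe$within[["within_2fold"]]
        out$within_3fold_test <- fe$within[["within_3fold"]]
        out$average_fold_test <- fe$average_fold
      }
    }
  } else {
    cv <- cross_validate(train_set, config, k, seed)
    out[c("ACC", "SP", "SE", "AUC", "kappa")] <-
      cv[c("ACC", "SP", "SE", "AUC", "kappa")]
    if (!is.null(test_set)) {
      tp <- predict(model, test_set$features)
      tm <- classification_metrics(test_set$y, tp$probability)
      out$ACC_T <- tm$ACC; out$SP_T <- tm$SP; out$SE_T <- tm$SE
      out$AUC_T <- tm$AUC; out$kappa_T <- tm$kappa
    }
  }
  structure(out, class = "eval_report", model = model)
}
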