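# Model training: six algorithms behind one train()/predict() surface,
# two-stage grid searches with the canonical schedules, and the two
# imbalance-handling strategies (balanced per-tree sampling, resampling
# consensus).

REGRESSION_ALGOS <- c("rf", "svm_rbf", "pls", "cart_regression")
CLASSIFICATION_ALGOS <- c("rf", "svm_rbf", "naive_bayes", "decision_tree")

#' Model configuration
#'
#' @param algorithm One of `rf`, `svm_rbf`, `pls`, `cart_regression`,
#'   `naive_bayes`, `decision_tree`.
#' @param task `"regression"` or `"classification"`. Regression supports
#'   rf/svm_rbf/pls/cart_regression; classification supports
#'   rf/svm_rbf/naive_bayes/decision_tree.
#' @param hyperparameters Named list; recognised entries: `estimators`
#'   (trees), `mtry`, `C` and `Sigma` (RBF SVM, kernel
#'   `exp(-||x-z||^2 / (2 Sigma^2))`), `n_components` (PLS), `samplesize`.
#' @param seed Integer seed used by every stochastic fit.
#' @return A `model_config`.
#' @export
model_config <- function(algorithm, task = c("regression", "classification"),
                         hyperparameters = list(), seed = 1L) {
  task <- match.arg(task)
  allowed <- if (task == "regression") REGRESSION_ALGOS else
    CLASSIFICATION_ALGOS
  if (!algorithm %in% allowed)
    stop("algorithm '", algorithm, "' is not available for ", task,
         " (choose one of: ", paste(allowed, collapse = ", "), ")")
  structure(list(algorithm = algorithm, task = task,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "model_config")
}

.standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

#' Train a model
#'
#' Fits the configured algorithm on a labeled dataset. Features are
#' z-score standardized internally for SVM and PLS using training
#' statistics. Classification models expose probabilities in `[0, 1]`.
#' Training is deterministic given (`dataset`, `config`).
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [model_config()] compatible with the dataset's task.
#' @return A `trained_model`.
#' @export
train <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "model_config"))
  if (config$task != dataset$task)
    stop("config task (", config$task, ") does not match dataset task (",
         dataset$task, ")")
  X <- unclass(dataset$features)
  y <- dataset$y
  hp <- config$hyperparameters
  task <- config$task
  clf <- task == "classification"
  set.seed(config$seed)
  extra <- list(fp_kind = attr(dataset$features, "kind"))

  fitted <- switch(config$algorithm,
    rf = {
      randomForest::randomForest(
        x = X, y = if (clf) factor(y, levels = c(0, 1)) else y,
        ntree = hp$estimators %||% 500L,
        mtry = hp$mtry %||% max(1L, floor(sqrt(ncol(X)))))
    },
    svm_rbf = {
      st <- .standardize_fit(X)
      extra$standardize <- st
      sigma <- hp$Sigma %||% 1
      e1071::svm(
        x = .standardize_apply(X, st),
        y = if (clf) factor(y, levels = c(0, 1)) else y,
        type = if (clf) "C-classification" else "eps-regression",
        kernel = "radial", cost = hp$C %||% 1,
        gamma = 1 / (2 * sigma^2), scale = FALSE,
        probability = clf)
    },
    pls = {
      st <- .standardize_fit(X)
      extra$standardize <- st
      ncomp <- hp$n_components %||% min(10L, ncol(X), nrow(X) - 2L)
      extra$ncomp <- ncomp
      mixOmics::pls(.standardize_apply(X, st), y, ncomp = ncomp,
                    mode = "regression", scale = FALSE)
    },
    cart_regression = ,
    decision_tree = {
      df <- data.frame(.y = if (clf) factor(y, levels = c(0, 1)) else y,
                       X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df,
                   method = if (clf) "class" else "anova")
    },
    naive_bayes = {
      fp <- identical(attr(dataset$features, "kind"), "fingerprint")
      extra$bernoulli <- fp
      df <- if (fp)
        as.data.frame(lapply(as.data.frame(X), function(col)
          factor(col, levels = c(0, 1))), check.names = FALSE)
      else as.data.frame(X)
      names(df) <- colnames(X)
      e1071::naiveBayes(x = df, y = factor(y, levels = c(0, 1)),
                        laplace = 1)
    },
    stop("unknown algorithm: ", config$algorithm))

  summary <- list(n = nrow(X), p = ncol(X))
  model <- structure(list(config = config, feature_names = colnames(X),
                          fitted = fitted, extra = extra, task = task,
                          training_summary = summary),
                     class = "trained_model")
  preds <- predict(model, dataset$features)
  summary$fit_score <- if (clf)
    mean((preds$label == y)) else
    1 - sum((preds - y)^2) / max(sum((y - mean(y))^2), 1e-12)
  model$training_summary <- summary
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_features <- function(model, features) {
  X <- if (inherits(features, "feature_matrix") || is.matrix(features))
    unclass(features) else as.matrix(features)
  missing <- setdiff(model$feature_names, colnames(X))
  extra <- setdiff(colnames(X), model$feature_names)
  if (length(missing) || length(extra))
    stop("feature mismatch; missing: [",
         paste(head(missing, 5), collapse = ", "), "], unexpected: [",
         paste(head(extra, 5), collapse = ", "), "]")
  X[, model$feature_names, drop = FALSE]
}

#' Predict from a trained model
#'
#' @param object A `trained_model`.
#' @param features A [feature_matrix] (or matrix) whose columns exactly
#'   match the model's `feature_names`.
#' @param ... Unused.
#' @return Regression: a numeric vector. Classification: a data.frame with
#'   `probability` and `label` (probability >= 0.5).
#' @export
predict.trained_model <- function(object, features, ...) {
  X <- .check_features(object, features)
  clf <- object$task == "classification"
  prob <- switch(object$config$algorithm,
    rf = {
      if (clf) predict(object$fitted, X, type = "prob")[, "1"]
      else return(as.numeric(predict(object$fitted, X)))
    },
    svm_rbf = {
      Xs <- .standardize_apply(X, object$extra$standardize)
      if (clf) {
        pr <- predict(object$fitted, Xs, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      } else return(as.numeric(predict(object$fitted, Xs)))
    },
    pls = {
      Xs <- .standardize_apply(X, object$extra$standardize)
      pr <- predict(object$fitted, Xs)$predict
      return(as.numeric(pr[, 1, object$extra$ncomp]))
    },
    cart_regression = {
      return(as.numeric(predict(object$fitted,
                                data.frame(X, check.names = FALSE))))
    },
    decision_tree = {
      predict(object$fitted, data.frame(X, check.names = FALSE),
              type = "prob")[, "1"]
    },
    naive_bayes = {
      df <- if (isTRUE(object$extra$bernoulli))
        as.data.frame(lapply(as.data.frame(X), function(col)
          factor(col, levels = c(0, 1))))
      else as.data.frame(X)
      names(df) <- colnames(X)
      predict(object$fitted, df, type = "raw")[, "1"]
    })
  prob <- pmin(pmax(as.numeric(prob), 0), 1)
  data.frame(probability = prob, label = as.integer(prob >= 0.5))
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: %s %s, p=%d>\n", x$config$algorithm,
              x$task, length(x$feature_names)))
  invisible(x)
}

# ---- grid construction (pure functions, unit-testable) ----

#' Canonical grid schedules
#'
#' Pure constructors for the two-stage grid-search schedules. Stage 1 for
#' the random forest crosses `estimators` in \{500, 1000\} with an `mtry`
#' ladder starting at 1 with step 20 up to `p`; stage 2 rescans
#' `mtry' - 50 .. mtry' + 50` at step 2, clipped to `[1, p]`. Stage 1 for
#' the RBF SVM uses exponent ladders `C = 2^(-5), 2^(-3), ..., 2^15` and
#' `Sigma = 2^(-15), ..., 2^3`; stage 2 rescans both exponents within
#' best +/- 2 at step 0.25. The PLS grid is `1 .. min(100, p, n - 2)`.
#'
#' @param p Number of features.
#' @param best_mtry,best_exp Stage-1 optimum around which stage 2 scans.
#' @param n Number of training compounds (PLS cap).
#' @return Integer or numeric vector of grid points (exponents for the
#'   SVM ladders).
#' @name grid_schedules
NULL

#' @rdname grid_schedules
#' @export
rf_stage1_mtry_grid <- function(p) seq(1L, max(1L, p), by = 20L)

#' @rdname grid_schedules
#' @export
rf_stage2_mtry_grid <- function(best_mtry, p) {
  s <- seq(best_mtry - 50L, best_mtry + 50L, by = 2L)
  s[s >= 1L & s <= p]
}

#' @rdname grid_schedules
#' @export
svm_stage1_C_exponents <- function() seq(-5, 15, by = 2)

#' @rdname grid_schedules
#' @export
svm_stage1_sigma_exponents <- function() seq(-15, 3, by = 2)

#' @rdname grid_schedules
#' @export
svm_stage2_exponents <- function(best_exp) seq(best_exp - 2, best_exp + 2,
                                               by = 0.25)

#' @rdname grid_schedules
#' @export
pls_component_grid <- function(p, n) seq_len(min(100L, p, n - 2L))

grid_result <- function(stage1_grid, stage2_grid, stage1_best, final_best,
                        cv_scores) {
  structure(list(stage1_grid = stage1_grid, stage2_grid = stage2_grid,
                 stage1_best = stage1_best, final_best = final_best,
                 cv_scores = cv_scores),
            class = "grid_result")
}

# Shared CV machinery: mean score (Q2 / ACC) of a configuration. For
# classification the folds are re-drawn (up to 3 attempts) if a training
# fold degenerates to a single class.
.cv_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

.grid_cv_score <- function(dataset, config, k, seed) {
  X <- unclass(dataset$features); y <- dataset$y
  clf <- dataset$task == "classification"
  for (attempt in 0:2) {
    fold <- .cv_folds(nrow(X), k, seed + attempt * 101L)
    if (!clf || all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2, logical(1)))) {
      oof <- numeric(nrow(X))
      for (f in seq_len(k)) {
        tr <- fold != f
        sub <- labeled_dataset(
          feature_matrix(X[tr, , drop = FALSE], attr(dataset$features,
                                                     "kind"),
                         attr(dataset$features, "family")),
          y[tr], dataset$endpoint, dataset$task)
        m <- train(sub, config)
        pr <- predict(m, X[!tr, , drop = FALSE])
        oof[!tr] <- if (clf) pr$probability else pr
      }
      return(if (clf) mean((oof >= 0.5) == (y == 1)) else
        1 - sum((oof - y)^2) / sum((y - mean(y))^2))
    }
  }
  stop("could not build CV folds with both classes in every training part")
}

#' Two-stage grid search for the random forest
#'
#' Stage 1 crosses `estimators` in \{500, 1000\} with the step-20 `mtry`
#' ladder; stage 2 rescans `mtry` around the stage-1 optimum at step 2
#' (window clipped to `[1, p]`). Points are scored by `cv_folds`-fold CV
#' (Q2 for regression, accuracy for classification).
#'
#' @param dataset A [labeled_dataset()].
#' @param cv_folds CV folds (default 5).
#' @param seed Integer seed.
#' @return A `grid_result`; `final_best` holds `estimators` and `mtry`.
#' @export
grid_search_rf <- function(dataset, cv_folds = 5L, seed = 1L) {
  p <- ncol(dataset$features)
  stopifnot(p >= 2)
  stage1 <- expand.grid(estimators = c(500L, 1000L),
                        mtry = rf_stage1_mtry_grid(p))
  scores1 <- apply(stage1, 1, function(row)
    .grid_cv_score(dataset, model_config("rf", dataset$task,
                                         list(estimators = row[["estimators"]],
                                              mtry = row[["mtry"]]), seed),
                   cv_folds, seed))
  b1 <- stage1[which.max(scores1), ]
  stage2 <- expand.grid(estimators = b1$estimators,
                        mtry = rf_stage2_mtry_grid(b1$mtry, p))
  scores2 <- apply(stage2, 1, function(row)
    .grid_cv_score(dataset, model_config("rf", dataset$task,
                                         list(estimators = row[["estimators"]],
                                              mtry = row[["mtry"]]), seed),
                   cv_folds, seed))
  b2 <- stage2[which.max(scores2), ]
  grid_result(stage1, stage2,
              list(estimators = b1$estimators, mtry = b1$mtry),
              list(estimators = b2$estimators, mtry = b2$mtry),
              list(stage1 = scores1, stage2 = scores2))
}

#' Two-stage grid search for the RBF SVM
#'
#' Stage 1 scans the coarse exponent ladders (`C`: -5..15 step 2, `Sigma`:
#' -15..3 step 2); stage 2 jointly rescans both exponents within the
#' stage-1 best +/- 2 at step 0.25.
#'
#' @inheritParams grid_search_rf
#' @return A `grid_result`; `final_best` holds `C` and `Sigma`.
#' @export
grid_search_svm <- function(dataset, cv_folds = 5L, seed = 1L) {
  stage1 <- expand.grid(c_exp = svm_stage1_C_exponents(),
                        sigma_exp = svm_stage1_sigma_exponents())
  score_point <- function(ce, se)
    .grid_cv_score(dataset, model_config("svm_rbf", dataset$task,
                                         list(C = 2^ce, Sigma = 2^se), seed),
                   cv_folds, seed)
  scores1 <- mapply(score_point, stage1$c_exp, stage1$sigma_exp)
  b1 <- stage1[which.max(scores1), ]
  stage2 <- expand.grid(c_exp = svm_stage2_exponents(b1$c_exp),
                        sigma_exp = svm_stage2_exponents(b1$sigma_exp))
  scores2 <- mapply(score_point, stage2$c_exp, stage2$sigma_exp)
  b2 <- stage2[which.max(scores2), ]
  grid_result(stage1, stage2,
              list(C = 2^b1$c_exp, Sigma = 2^b1$sigma_exp),
              list(C = 2^b2$c_exp, Sigma = 2^b2$sigma_exp),
              list(stage1 = scores1, stage2 = scores2))
}

#' Grid search for PLS components
#'
#' Scans `n_components = 1 .. min(100, p, n - 2)`; the best component count
#' maximizes Q2, ties broken toward fewer components. Each fold is fitted
#' once at the maximum component count; predictions for every smaller count
#' fall out of the same fit.
#'
#' @inheritParams grid_search_rf
#' @return A `grid_result`; `final_best` holds `n_components`.
#' @export
grid_search_pls <- function(dataset, cv_folds = 5L, seed = 1L) {
  stopifnot(dataset$task == "regression")
  X <- unclass(dataset$features); y <- dataset$y
  if (ncol(X) == 0) stop("no features for PLS")
  grid <- pls_component_grid(ncol(X), nrow(X))
  kmax <- max(grid)
  fold <- .cv_folds(nrow(X), cv_folds, seed)
  oof <- matrix(NA_real_, nrow(X), kmax)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    st <- .standardize_fit(X[tr, , drop = FALSE])
    fit <- mixOmics::pls(.standardize_apply(X[tr, , drop = FALSE], st),
                         y[tr], ncomp = kmax, mode = "regression",
                         scale = FALSE)
    pr <- predict(fit, .standardize_apply(X[!tr, , drop = FALSE],
                                          st))$predict
    oof[!tr, ] <- pr[, 1, , drop = TRUE]
  }
  q2 <- vapply(grid, function(k)
    1 - sum((oof[, k] - y)^2) / sum((y - mean(y))^2), numeric(1))
  best <- grid[which.max(q2)]
  grid_result(grid, integer(0), list(n_components = best),
              list(n_components = best), list(stage1 = q2))
}

#' Balanced random forest via per-tree class sampling
#'
#' Every tree is grown on exactly `samplesize` positive and `samplesize`
#' negative compounds, drawn without replacement within each class, so the
#' per-tree class balance is 1:1 regardless of the dataset imbalance. The
#' number of trees is chosen (or checked) so every training compound is
#' expected to appear in at least one tree's sample with probability
#' at least 0.99.
#'
#' @param dataset A classification [labeled_dataset()].
#' @param samplesize Per-class per-tree sample size; default
#'   `min(100, minority class size)`.
#' @param estimators Number of trees; when `NULL`, computed from the
#'   coverage rule (at least 500).
#' @param seed Integer seed.
#' @return A `trained_model` whose `extra$inbag` records per-tree sample
#'   membership.
#' @export
train_balanced_rf <- function(dataset, samplesize = NULL, estimators = NULL,
                              seed = 1L) {
  stopifnot(dataset$task == "classification")
  y <- dataset$y
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos < 2 || n_neg < 2)
    stop("both classes need at least 2 members")
  m <- min(n_pos, n_neg)
  samplesize <- samplesize %||% min(100L, m)
  if (samplesize > m)
    stop("samplesize (", samplesize, ") exceeds the minority class (", m,
         ") and sampling is without replacement")
  # trees needed so P(compound never sampled) <= 0.01 in the larger class
  worst <- max(n_pos, n_neg)
  needed <- if (samplesize >= worst) 1L else
    as.integer(ceiling(log(0.01) / log(1 - samplesize / worst)))
  if (is.null(estimators)) {
    estimators <- max(500L, needed)
  } else if (estimators < needed) {
    warning("with ", estimators, " trees some compounds may never be ",
            "sampled (", needed, " trees needed for 0.99 coverage)")
  }
  X <- unclass(dataset$features)
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)), ntree = estimators,
    strata = factor(y, levels = c(0, 1)),
    sampsize = c(`0` = samplesize, `1` = samplesize),
    replace = FALSE, keep.inbag = TRUE)
  cfg <- model_config("rf", "classification",
                      list(estimators = estimators,
                           samplesize = samplesize), seed)
  structure(list(config = cfg, feature_names = colnames(X), fitted = fit,
                 extra = list(inbag = fit$inbag, y = y),
                 task = "classification",
                 training_summary = list(n = nrow(X), p = ncol(X),
                                         samplesize = samplesize)),
            class = "trained_model")
}

#' Resampling consensus for imbalanced classification
#'
#' Trains `n_members` models, each on all minority-class compounds plus an
#' equally sized without-replacement subsample of the majority class, and
#' aggregates them as the arithmetic mean of member probabilities (label at
#' 0.5).
#'
#' @param dataset A classification [labeled_dataset()].
#' @param n_members Ensemble size (default 10).
#' @param seed Integer seed.
#' @param member_config Optional [model_config()] template for members
#'   (default: 500-tree random forest).
#' @return A `consensus_model` holding the member `trained_model`s.
#' @export
train_resampling_consensus <- function(dataset, n_members = 10L, seed = 1L,
                                       member_config = NULL) {
  stopifnot(dataset$task == "classification")
  y <- dataset$y
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("single-class data")
  ratio <- max(n_pos, n_neg) / min(n_pos, n_neg)
  if (ratio < 1.2)
    warning("classes are nearly balanced (ratio ", round(ratio, 2),
            "); resampling consensus adds little")
  minority <- which(y == (if (n_pos <= n_neg) 1 else 0))
  majority <- setdiff(seq_along(y), minority)
  X <- unclass(dataset$features)
  members <- vector("list", n_members)
  seed <- seed %% 2000000L  # derived member seeds stay inside 32-bit range
  for (i in seq_len(n_members)) {
    set.seed(seed * 1000L + i)
    sub <- sort(c(minority,
                  majority[sample.int(length(majority),
                                      min(length(minority),
                                          length(majority)))]))
    ds <- labeled_dataset(
      feature_matrix(X[sub, , drop = FALSE],
                     attr(dataset$features, "kind"),
                     attr(dataset$features, "family")),
      y[sub], dataset$endpoint, "classification")
    cfg <- member_config %||%
      model_config("rf", "classification", list(estimators = 500L),
                   seed * 1000L + i)
    cfg$seed <- seed * 1000L + i
    members[[i]] <- train(ds, cfg)
  }
  structure(list(members = members,
                 feature_names = members[[1]]$feature_names,
                 task = "classification", aggregation = "mean_probability"),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model: %d members (%s)>\n", length(x$members),
              x$aggregation))
  invisible(x)
}

#' Predict from a consensus model
#'
#' The consensus probability is the arithmetic mean of member
#' probabilities; the label is assigned at 0.5.
#'
#' @param object A `consensus_model`.
#' @param features Features matching the members' `feature_names`.
#' @param ... Unused.
#' @return A data.frame with `probability` and `label`.
#' @export
predict.consensus_model <- function(object, features, ...) {
  probs <- vapply(object$members, function(m)
    predict(m, features)$probability,
    numeric(nrow(features)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  p <- rowMeans(probs)
  data.frame(probability = p, label = as.integer(p >= 0.5))
}
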