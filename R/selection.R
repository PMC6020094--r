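# Descriptor selection: the three-rule pre-filter followed by recursive
# feature elimination driven by random-forest importance.

#' Three-rule descriptor pre-filter
#'
#' Applies, in order: (1) remove descriptors with zero or near-zero
#' variance; (2) remove descriptors whose most frequent value accounts for
#' more than `identity_threshold` of the rows; (3) for every pair with
#' Pearson |r| above `corr_threshold`, remove one member. Near-zero
#' variance is judged scale-free: a column is removed when its variance
#' after division by its largest absolute value falls below `var_eps`.
#' With a `seed`, rule 3 removes a random member of each offending pair;
#' without one it removes the later column in name order.
#'
#' @param matrix A descriptor [feature_matrix].
#' @param var_eps Near-zero variance tolerance (default 1e-8).
#' @param identity_threshold Maximum modal-value frequency (default 0.95).
#' @param corr_threshold Maximum absolute pairwise correlation (default
#'   0.95).
#' @param seed Optional integer seed for rule 3 tie resolution.
#' @return List with the filtered `matrix` and a `report` containing
#'   `removed_zero_variance`, `removed_high_identity`, `removed_correlated`
#'   (kept name, removed name, r) and `surviving`.
#' @export
prefilter <- function(matrix, var_eps = 1e-8, identity_threshold = 0.95,
                      corr_threshold = 0.95, seed = NULL) {
  X <- unclass(matrix)
  cols <- colnames(X)

  # rule 1: zero / near-zero variance (scale-free)
  v <- apply(X, 2, function(x) {
    mx <- max(abs(x))
    if (mx == 0) 0 else var(x / mx)
  })
  rm1 <- cols[v <= var_eps]
  alive <- setdiff(cols, rm1)

  # rule 2: modal value frequency > threshold
  frac_modal <- vapply(alive, function(nm)
    max(table(X[, nm])) / nrow(X), numeric(1))
  rm2 <- alive[frac_modal > identity_threshold]
  alive <- setdiff(alive, rm2)

  # rule 3: high pairwise correlation, scanned in column-name order
  rm3 <- data.frame(kept = character(), removed = character(),
                    r = numeric())
  if (length(alive) > 1) {
    if (!is.null(seed)) set.seed(seed)
    ord <- sort(alive)
    cm <- suppressWarnings(cor(X[, ord, drop = FALSE]))
    dead <- character(0)
    for (i in seq_len(length(ord) - 1)) {
      if (ord[i] %in% dead) next
      for (j in seq(i + 1, length(ord))) {
        if (ord[j] %in% dead) next
        r <- cm[i, j]
        if (is.finite(r) && abs(r) > corr_threshold) {
          drop_j <- if (is.null(seed)) TRUE else sample(c(TRUE, FALSE), 1)
          kept <- if (drop_j) ord[i] else ord[j]
          gone <- if (drop_j) ord[j] else ord[i]
          dead <- c(dead, gone)
          rm3 <- rbind(rm3, data.frame(kept = kept, removed = gone, r = r))
          if (!drop_j) break
        }
      }
    }
    alive <- setdiff(alive, dead)
  }
  if (length(alive) == 0) stop("no informative descriptors remain")
  report <- list(removed_zero_variance = rm1, removed_high_identity = rm2,
                 removed_correlated = rm3,
                 surviving = cols[cols %in% alive])
  list(matrix = fm_select(matrix, report$surviving), report = report)
}

.rf_fit <- function(X, y, task, estimators, mtry, seed) {
  ranger::ranger(
    x = as.data.frame(X), y = if (task == "classification")
      factor(y, levels = c(0, 1)) else y,
    num.trees = estimators, mtry = mtry, importance = "impurity",
    probability = task == "classification",
    num.threads = 1, seed = seed)
}

.rf_predict <- function(fit, X, task) {
  pr <- predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
  if (task == "classification") pr[, "1"] else pr
}

# Internal k-fold CV score for the RFE path: Q2 for regression (against the
# mean of the full label vector), ACC for classification.
.rfe_cv_score <- function(X, y, task, estimators, k, seed) {
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  oof <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- .rf_fit(X[tr, , drop = FALSE], y[tr], task, estimators,
                   max(1L, floor(sqrt(ncol(X)))), seed + f)
    oof[!tr] <- .rf_predict(fit, X[!tr, , drop = FALSE], task)
  }
  if (task == "regression") {
    1 - sum((oof - y)^2) / sum((y - mean(y))^2)
  } else {
    mean((oof >= 0.5) == (y == 1))
  }
}

#' Random-forest recursive feature elimination
#'
#' Starting from all features, fits a random forest (`estimators` trees,
#' `mtry = floor(sqrt(p))`), ranks features by impurity importance, removes
#' the `step` least important, and repeats until two features remain. Each
#' step records the cross-validated score (Q2 for regression, accuracy for
#' classification) of a forest restricted to the surviving features.
#'
#' @param dataset A [labeled_dataset()].
#' @param cv_folds Number of CV folds (default 5).
#' @param step Features removed per iteration (default 2).
#' @param estimators Trees per forest (default 1000).
#' @param seed Integer seed; the step index is folded in so the whole path
#'   is reproducible.
#' @return An `rfe_path`: list of `steps` (each with `n_features`,
#'   `features`, `cv_score`, `ranking`) and `best_index`.
#' @export
rf_rfe <- function(dataset, cv_folds = 5L, step = 2L, estimators = 1000L,
                   seed = 1L) {
  X <- unclass(dataset$features)
  y <- dataset$y
  task <- dataset$task
  feats <- colnames(X)
  steps <- list()
  s <- 0L
  repeat {
    s <- s + 1L
    Xc <- X[, feats, drop = FALSE]
    step_seed <- (seed %% 2000000L) * 1000L + s  # stays inside 32-bit range
    fit <- .rf_fit(Xc, y, task, estimators,
                   max(1L, floor(sqrt(length(feats)))), step_seed)
    imp <- ranger::importance(fit)
    if (any(!is.finite(imp))) stop("non-finite feature importance")
    cv <- .rfe_cv_score(Xc, y, task, estimators, cv_folds, step_seed)
    ranking <- names(sort(imp, decreasing = TRUE))
    steps[[s]] <- list(n_features = length(feats), features = feats,
                       cv_score = cv, ranking = ranking)
    if (length(feats) <= 2L) break
    drop_n <- min(step, length(feats) - 2L)
    feats <- setdiff(feats, rev(ranking)[seq_len(drop_n)])
  }
  scores <- vapply(steps, `[[`, numeric(1), "cv_score")
  sizes <- vapply(steps, `[[`, numeric(1), "n_features")
  best <- which(scores == max(scores))
  best <- best[which.min(sizes[best])]
  structure(list(steps = steps, best_index = best), class = "rfe_path")
}

#' @export
print.rfe_path <- function(x, ...) {
  sizes <- vapply(x$steps, `[[`, numeric(1), "n_features")
  scores <- vapply(x$steps, `[[`, numeric(1), "cv_score")
  cat(sprintf("<rfe_path: %d steps, sizes %d..%d, best %d features (score %.3f)>\n",
              length(x$steps), max(sizes), min(sizes),
              x$steps[[x$best_index]]$n_features, scores[x$best_index]))
  invisible(x)
}

#' Best feature set of an RFE path
#'
#' The step with the maximal cross-validated score; ties are broken toward
#' fewer features.
#'
#' @param path An `rfe_path` from [rf_rfe()].
#' @return Character vector of selected feature names.
#' @export
select_best <- function(path) {
  stopifnot(inherits(path, "rfe_path"), length(path$steps) > 0)
  path$steps[[path$best_index]]$features
}
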