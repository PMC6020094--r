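#' Labeled datasets
#'
#' Couples a [feature_matrix] with endpoint labels: continuous values for
#' regression, 0/1 for classification.
#'
#' @param features A [feature_matrix].
#' @param y Numeric label vector, one per feature row.
#' @param endpoint Endpoint name.
#' @param task `"regression"` or `"classification"`.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(features, y, endpoint = "endpoint",
                            task = c("regression", "classification")) {
  task <- match.arg(task)
  stopifnot(inherits(features, "feature_matrix"), length(y) == nrow(features))
  if (task == "classification" && !all(y %in% c(0, 1)))
    stop("classification labels must be 0/1")
  if (task == "regression" && any(!is.finite(y)))
    stop("regression labels must be finite")
  structure(list(features = features, y = as.numeric(y),
                 endpoint = endpoint, task = task),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset '%s': %s, n=%d, p=%d>\n", x$endpoint,
              x$task, nrow(x$features), ncol(x$features)))
  invisible(x)
}

aggregation_report <- function(merged, dropped) {
  structure(list(merged = merged, dropped = dropped),
            class = "aggregation_report")
}

#' Deduplicate a classification dataset
#'
#' Compounds are grouped by canonical SMILES. Groups carrying one distinct
#' label keep a single entry with that label; groups with conflicting labels
#' are dropped (`CONFLICTING_LABELS`) rather than choosing a label
#' arbitrarily. Entries with missing labels are dropped
#' (`NO_EXPLICIT_VALUE`).
#'
#' @param records List of canonicalized [molecule_record()]s.
#' @param labels Binary (0/1) label vector aligned with `records`.
#' @return List with deduplicated `records`, `labels`, and `report`
#'   (an `aggregation_report`).
#' @export
deduplicate_classification <- function(records, labels) {
  stopifnot(length(records) == length(labels))
  if (!all(labels %in% c(0, 1, NA)))
    stop("classification labels must be binary 0/1")
  smis <- vapply(records, `[[`, character(1), "smiles")
  merged <- data.frame(smiles = character(), n_entries = integer(),
                       value = numeric())
  dropped <- data.frame(smiles = character(), reason = character())
  keep_rec <- list(); keep_lab <- numeric(0)
  for (smi in unique(smis)) {
    idx <- which(smis == smi)
    labs <- labels[idx]
    if (all(is.na(labs))) {
      dropped <- rbind(dropped,
                       data.frame(smiles = smi, reason = "NO_EXPLICIT_VALUE"))
      next
    }
    labs <- labs[!is.na(labs)]
    if (length(unique(labs)) > 1) {
      dropped <- rbind(dropped,
                       data.frame(smiles = smi,
                                  reason = "CONFLICTING_LABELS"))
      next
    }
    keep_rec[[length(keep_rec) + 1L]] <- records[[idx[1]]]
    keep_lab <- c(keep_lab, labs[1])
    if (length(idx) > 1)
      merged <- rbind(merged, data.frame(smiles = smi,
                                         n_entries = length(idx),
                                         value = labs[1]))
  }
  list(records = keep_rec, labels = keep_lab,
       report = aggregation_report(merged, dropped))
}

#' Aggregate duplicate regression measurements
#'
#' Duplicate groups (same canonical SMILES) whose relative spread
#' `(max - min) / |mean|` does not exceed `rel_spread_limit` are merged to
#' their arithmetic mean; wider groups are deleted (`EXCESS_SPREAD`). When a
#' group mean is numerically zero the absolute range is compared against
#' `abs_eps` instead. Missing values drop the entry (`NO_EXPLICIT_VALUE`).
#'
#' @param records List of canonicalized [molecule_record()]s.
#' @param values Numeric endpoint values aligned with `records`.
#' @param rel_spread_limit Maximum tolerated relative spread (default 0.5).
#' @param abs_eps Absolute fallback tolerance when the mean is 0.
#' @return List with `records`, `values`, and `report`.
#' @export
aggregate_regression <- function(records, values, rel_spread_limit = 0.5,
                                 abs_eps = 1e-8) {
  stopifnot(length(records) == length(values))
  smis <- vapply(records, `[[`, character(1), "smiles")
  merged <- data.frame(smiles = character(), n_entries = integer(),
                       value = numeric())
  dropped <- data.frame(smiles = character(), reason = character())
  keep_rec <- list(); keep_val <- numeric(0)
  for (smi in unique(smis)) {
    idx <- which(smis == smi)
    vals <- values[idx]
    if (all(!is.finite(vals))) {
      dropped <- rbind(dropped,
                       data.frame(smiles = smi, reason = "NO_EXPLICIT_VALUE"))
      next
    }
    vals <- vals[is.finite(vals)]
    if (length(vals) > 1) {
      m <- mean(vals)
      spread_ok <- if (abs(m) <= abs_eps)
        (max(vals) - min(vals)) <= abs_eps
      else (max(vals) - min(vals)) / abs(m) <= rel_spread_limit
      if (!spread_ok) {
        dropped <- rbind(dropped,
                         data.frame(smiles = smi, reason = "EXCESS_SPREAD"))
        next
      }
      merged <- rbind(merged, data.frame(smiles = smi,
                                         n_entries = length(idx),
                                         value = m))
      vals <- m
    }
    keep_rec[[length(keep_rec) + 1L]] <- records[[idx[1]]]
    keep_val <- c(keep_val, vals)
  }
  list(records = keep_rec, values = keep_val,
       report = aggregation_report(merged, dropped))
}

#' Diversity-based train/test split
#'
#' Selects the training set by max-min (Kennard-Stone-style) diversity
#' picking on Tanimoto distance over fingerprint bits, so training compounds
#' cover chemical space. The first pick is the molecule with the highest
#' mean distance to all others (ties by row order); each further pick
#' maximizes the minimum distance to the already-selected set, exact ties
#' broken randomly under `seed`. The training size is `fraction * n`,
#' rounded half up.
#'
#' @param features A [feature_matrix] of fingerprint bits (ECFP4 is the
#'   package convention, see [compute_fingerprints()]).
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed (used only for exact-distance ties).
#' @return A `split_result` with `train_ids`, `test_ids`, `fraction`,
#'   `seed`.
#' @export
diverse_split <- function(features, fraction = 0.75, seed = 1L) {
  n <- nrow(features)
  if (n < 4) stop("too few molecules to split (n < 4)")
  stopifnot(fraction > 0, fraction < 1)
  ids <- rownames(features)
  X <- unclass(features)
  # pairwise Tanimoto distance on bit rows
  inter <- X %*% t(X)
  ones <- rowSums(X)
  uni <- outer(ones, ones, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 1)
  D <- 1 - sim

  n_train <- floor(fraction * n + 0.5)
  set.seed(seed)
  mean_d <- rowMeans(D)
  first <- which(mean_d == max(mean_d))[1]
  selected <- first
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < n_train) {
    mind <- apply(D[remaining, selected, drop = FALSE], 1, min)
    best <- remaining[mind == max(mind)]
    pick <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(train_ids = ids[sort(selected)],
                 test_ids = ids[sort(remaining)],
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result: %d train / %d test (fraction %.2f)>\n",
              length(x$train_ids), length(x$test_ids), x$fraction))
  invisible(x)
}
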