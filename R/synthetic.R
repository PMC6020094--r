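# Synthetic data with known ground truth: a fragment-grammar molecule
# corpus for the structure-handling modules, and linear-model feature/label
# datasets for the selection, modeling and evaluation modules.

# Aromatic / aliphatic cores with one substitution point, and a substituent
# alphabet of common functional groups. Molecules are assembled by
# sprintf-ing substituents into cores, so every generated SMILES is valid
# by construction.
.corpus_cores <- function() {
  c("c1ccc(%s)cc1", "c1ccc(%s)nc1", "c1ccc(%s)o1", "c1ccc(%s)s1",
    "C1CCC(%s)CC1", "C1CCN(%s)CC1", "C1CCOC1%s",
    "c1cc(%s)c2ccccc2c1", "C(%s)C1CC1", "CC(C)(%s)C", "C1CCCCC1%s",
    "c1cnc(%s)nc1", "CCCC%s", "CC(C)C%s", "CCOCC%s", "C1CN(%s)CCO1")
}

.corpus_subs <- function() {
  c("C", "CC", "CCC", "CCO", "CO", "CN", "CCN", "O", "N", "OC", "Cl", "F",
    "Br", "C(=O)O", "C(=O)N", "C(=O)OC", "C(=O)C", "S", "SC", "C#N",
    "C(F)(F)F", "CC(C)C", "OCC", "NC(=O)C", "CCCO", "CCl", "C=C",
    "N(C)C", "CCS", "COC")
}

#' Generate a synthetic molecule corpus
#'
#' Assembles `n` distinct valid molecules from a bundled fragment grammar
#' (ring cores plus a substituent alphabet); distinctness is enforced on
#' canonical SMILES. With `include_salts`, 20% of the records (rounded up)
#' are emitted as multi-fragment salt forms: carboxylic acids become their
#' sodium carboxylates, other molecules gain a hydrochloride counter-ion.
#' Deterministic for a given `seed`.
#'
#' @param n Number of molecules (errors if the grammar cannot produce
#'   enough distinct structures).
#' @param seed Integer seed.
#' @param include_salts Emit 20% of records as salts (for wash tests).
#' @return List of [molecule_record()]s, ids `syn_0001` ...
#' @export
generate_molecule_corpus <- function(n, seed = 1L, include_salts = FALSE) {
  stopifnot(n >= 1)
  cores <- .corpus_cores()
  subs <- .corpus_subs()
  max_space <- length(cores) * length(subs)
  if (n > max_space)
    stop("corpus grammar can produce at most ", max_space,
         " distinct molecules")
  set.seed(seed)
  seen <- character(0)
  smiles <- character(0)
  attempts <- 0L
  while (length(smiles) < n && attempts < 50L * n) {
    attempts <- attempts + 1L
    smi <- sprintf(sample(cores, 1), sample(subs, 1))
    can <- ob_canonical(smi)
    if (is.na(can) || can %in% seen) next
    seen <- c(seen, can)
    smiles <- c(smiles, can)
  }
  if (length(smiles) < n)
    stop("could not assemble ", n, " distinct molecules (got ",
         length(smiles), ")")
  if (include_salts) {
    n_salt <- ceiling(0.2 * n)
    salt_idx <- sample.int(n, n_salt)
    for (i in salt_idx) {
      smi <- smiles[i]
      # terminal carboxylic acids become sodium carboxylates; everything
      # else gets a hydrochloride counter-ion
      smiles[i] <- if (grepl("C\\(=O\\)O(?![A-Za-z])", smi, perl = TRUE))
        paste0(sub("C\\(=O\\)O(?![A-Za-z])", "C(=O)[O-]", smi, perl = TRUE),
               ".[Na+]")
      else paste0(smi, ".Cl")
    }
  }
  lapply(seq_len(n), function(i)
    molecule_record(smiles[i], id = sprintf("syn_%04d", i),
                    source_index = i - 1L))
}

#' Synthetic QSAR dataset specification
#'
#' @param n Number of compounds.
#' @param task `"regression"` or `"classification"`.
#' @param n_features Total feature count.
#' @param n_informative Number of features carrying signal.
#' @param effect_sizes Coefficients of the informative features; default
#'   magnitudes evenly spaced in `[1, 2]` with alternating signs.
#' @param noise_sigma Gaussian noise standard deviation on the linear
#'   score.
#' @param class_balance Positive-class fraction (classification only).
#' @param seed Integer seed; the dataset is reproducible from the spec
#'   alone.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n, task = c("regression", "classification"),
                           n_features = 50L, n_informative = 5L,
                           effect_sizes = NULL, noise_sigma = 0.5,
                           class_balance = 0.5, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_informative <= n_features, class_balance > 0,
            class_balance < 1)
  if (is.null(effect_sizes)) {
    effect_sizes <- seq(1, 2, length.out = max(1, n_informative)) *
      rep_len(c(1, -1), n_informative)
  }
  if (n_informative == 0 && any(effect_sizes != 0))
    stop("n_informative = 0 is incompatible with nonzero effect sizes")
  stopifnot(length(effect_sizes) == n_informative || n_informative == 0)
  structure(list(n = as.integer(n), task = task,
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_sizes = effect_sizes,
                 noise_sigma = noise_sigma,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic feature/label dataset
#'
#' Features are i.i.d. standard normal. The linear score is
#' `score = X[, informative] %*% effect_sizes + eps`,
#' `eps ~ N(0, noise_sigma^2)`. Regression uses the score as the label;
#' classification thresholds the logistic transform of the score at the
#' empirical quantile that yields exactly the requested positive fraction
#' (up to ties).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [labeled_dataset()]), `informative`
#'   (feature names carrying signal) and `coefficients`.
#' @export
generate_qsar_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  X <- matrix(rnorm(spec$n * spec$n_features), spec$n, spec$n_features)
  colnames(X) <- sprintf("feat_%03d", seq_len(spec$n_features))
  rownames(X) <- sprintf("cmp_%04d", seq_len(spec$n))
  informative <- colnames(X)[seq_len(spec$n_informative)]
  score <- if (spec$n_informative > 0)
    as.numeric(X[, informative, drop = FALSE] %*% spec$effect_sizes)
  else numeric(spec$n)
  score <- score + rnorm(spec$n, 0, spec$noise_sigma)
  fm <- feature_matrix(X, kind = "descriptor",
                       family = setNames(rep("synthetic", ncol(X)),
                                         colnames(X)))
  if (spec$task == "regression") {
    y <- score
  } else {
    p <- stats::plogis(score)
    thr <- quantile(p, 1 - spec$class_balance, type = 1)
    y <- as.numeric(p > thr)
  }
  list(dataset = labeled_dataset(fm, y, endpoint = "synthetic",
                                 task = spec$task),
       informative = informative,
       coefficients = setNames(spec$effect_sizes, informative))
}
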