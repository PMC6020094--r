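# Shared fixtures, built in code. Molecule parsing goes through Open Babel,
# so the small corpora used across files are memoised per session.

.fixture_env <- new.env()

fixture_corpus <- function(n = 20, seed = 42, include_salts = FALSE) {
  key <- paste("corpus", n, seed, include_salts, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_molecule_corpus(n, seed, include_salts)
  .fixture_env[[key]]
}

fixture_records <- function(smiles, ids = paste0("m", seq_along(smiles))) {
  mapply(molecule_record, smiles, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# A small labeled regression / classification dataset on synthetic features.
fixture_dataset <- function(task = "regression", n = 60, p = 8,
                            informative = 3, balance = 0.5, seed = 7) {
  generate_qsar_dataset(synthetic_spec(
    n, task, n_features = p, n_informative = informative,
    class_balance = balance, seed = seed))
}

random_bit_matrix <- function(n, width, seed, density = 0.2) {
  set.seed(seed)
  m <- matrix(as.integer(runif(n * width) < density), n, width)
  colnames(m) <- paste0("b", seq_len(width))
  rownames(m) <- sprintf("r%03d", seq_len(n))
  m
}
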