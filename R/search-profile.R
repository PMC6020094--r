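# Local ADMET record store: accurate / range / similarity search, plus the
# per-molecule systematic ADMET profile rendered from a model registry.

#' Load an ADMET record store
#'
#' Reads a CSV of ADMET records (columns: `entry_id`, `smiles`, and
#' optionally `cas`, `iupac_name`, `class`, `subclass`, `value`, `MW`,
#' `AlogP`, `HBA`, `HBD`, `reference`). SMILES are canonicalized at load;
#' MW/AlogP/HBA/HBD are computed from structure for entries where they are
#' absent, so range search always has them.
#'
#' @param path CSV file path.
#' @return An `admet_store` (data.frame subclass).
#' @export
load_admet_store <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("entry_id", "smiles") %in% names(tab)))
    stop("store must have 'entry_id' and 'smiles' columns")
  for (col in c("cas", "iupac_name", "class", "subclass", "value",
                "reference"))
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  can <- ob_canonical(tab$smiles)
  if (any(is.na(can)))
    stop("unparseable SMILES in store rows: ",
         paste(which(is.na(can)), collapse = ", "))
  tab$smiles <- can
  need <- c("MW", "AlogP", "HBA", "HBD")
  have <- need[need %in% names(tab)]
  missing_any <- !all(need %in% names(tab)) ||
    anyNA(tab[, have, drop = FALSE])
  if (missing_any) {
    recs <- lapply(seq_len(nrow(tab)), function(i)
      molecule_record(tab$smiles[i], id = as.character(tab$entry_id[i])))
    rd <- rule_descriptors(recs)
    if (!"MW" %in% names(tab) || anyNA(tab$MW)) tab$MW <- rd$MW
    if (!"AlogP" %in% names(tab) || anyNA(tab$AlogP)) tab$AlogP <- rd$LogP
    if (!"HBA" %in% names(tab) || anyNA(tab$HBA)) tab$HBA <- rd$HBA
    if (!"HBD" %in% names(tab) || anyNA(tab$HBD)) tab$HBD <- rd$HBD
  }
  class(tab) <- c("admet_store", "data.frame")
  tab
}

#' Accurate search by SMILES, CAS number or IUPAC name
#'
#' SMILES queries match by canonical form (any spelling of the same graph
#' matches); CAS and IUPAC queries match case-insensitively and exactly.
#' An absent key yields an empty result, not an error.
#'
#' @param store An `admet_store` from [load_admet_store()].
#' @param key_type One of `"smiles"`, `"cas"`, `"iupac"`.
#' @param key The query string.
#' @return The matching store rows.
#' @export
accurate_search <- function(store, key_type = c("smiles", "cas", "iupac"),
                            key) {
  key_type <- match.arg(key_type)
  hit <- switch(key_type,
    smiles = store$smiles == canonicalize(key),
    cas = !is.na(store$cas) & tolower(store$cas) == tolower(key),
    iupac = !is.na(store$iupac_name) &
      tolower(store$iupac_name) == tolower(key))
  store[which(hit), , drop = FALSE]
}

#' Range search over MW, AlogP, HBA, HBD
#'
#' Returns entries satisfying every supplied range simultaneously; bounds
#' are inclusive on both ends.
#'
#' @param store An `admet_store`.
#' @param ranges Named list over a subset of `MW`, `AlogP`, `HBA`, `HBD`;
#'   each element `c(lo, hi)`.
#' @return The matching store rows.
#' @examples
#' \dontrun{range_search(store, list(MW = c(150, 350), HBD = c(0, 5)))}
#' @export
range_search <- function(store, ranges) {
  if (length(ranges) == 0) stop("at least one range is required")
  bad <- setdiff(names(ranges), c("MW", "AlogP", "HBA", "HBD"))
  if (length(bad)) stop("unknown range key(s): ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(store))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("range for ", nm, " must be c(lo, hi) with lo <= hi")
    keep <- keep & store[[nm]] >= r[1] & store[[nm]] <= r[2]
  }
  store[which(keep), , drop = FALSE]
}

# Tanimoto / Dice similarity of one query bit row against a bit matrix.
.bit_similarity <- function(query_bits, mat, metric) {
  inter <- as.numeric(mat %*% query_bits)
  a <- sum(query_bits)
  b <- rowSums(mat)
  if (metric == "tanimoto") {
    denom <- a + b - inter
    ifelse(denom > 0, inter / denom, 0)
  } else {
    denom <- a + b
    ifelse(denom > 0, 2 * inter / denom, 0)
  }
}

#' Fingerprint similarity search
#'
#' Scores every store entry against the query molecule with Tanimoto
#' (`|A&B| / |A|B|`-union) or Dice (`2|A&B| / (|A|+|B|)`) similarity over
#' the chosen fingerprint, and returns hits sorted by descending score
#' (ties by entry id). A query with no bits set scores 0 everywhere, with
#' a warning.
#'
#' @param store An `admet_store`.
#' @param query A [molecule_record()].
#' @param fingerprint One of `"fp2"`, `"maccs"`, `"ecfp2"`, `"ecfp4"`,
#'   `"ecfp6"` (default `"ecfp4"`).
#' @param metric `"tanimoto"` or `"dice"`.
#' @param min_score Keep hits scoring at least this (optional).
#' @param top_k Keep at most this many hits (optional).
#' @return A data.frame of `entry_id`, `score`, `metric`, `fingerprint`.
#' @export
similarity_search <- function(store, query,
                              fingerprint = c("ecfp4", "fp2", "maccs",
                                              "ecfp2", "ecfp6"),
                              metric = c("tanimoto", "dice"),
                              min_score = NULL, top_k = NULL) {
  fingerprint <- match.arg(fingerprint)
  metric <- match.arg(metric)
  stopifnot(inherits(query, "molecule_record"))
  recs <- lapply(seq_len(nrow(store)), function(i)
    molecule_record(store$smiles[i], id = as.character(store$entry_id[i])))
  fm <- compute_fingerprints(recs, fingerprint)
  qfm <- compute_fingerprints(list(query), fingerprint)
  qbits <- as.numeric(unclass(qfm)[1, ])
  if (sum(qbits) == 0)
    warning("query fingerprint has no bits set; all scores are 0")
  score <- .bit_similarity(qbits, unclass(fm), metric)
  out <- data.frame(entry_id = as.character(store$entry_id), score = score,
                    metric = metric, fingerprint = fingerprint,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$entry_id), , drop = FALSE]
  if (!is.null(min_score)) out <- out[out$score >= min_score, , drop = FALSE]
  if (!is.null(top_k)) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Map a classification probability to a +/- symbol band
#'
#' `[0, 0.1] -> "---"`, `(0.1, 0.3] -> "--"`, `(0.3, 0.5] -> "-"`,
#' `(0.5, 0.7] -> "+"`, `(0.7, 0.9] -> "++"`, `(0.9, 1] -> "+++"`: the
#' symbol count tracks how decisively the probability sits in its class.
#'
#' @param p Probability in `[0, 1]`.
#' @return The symbol string.
#' @export
probability_symbol <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p <= 0.1) "---" else if (p <= 0.3) "--" else if (p <= 0.5) "-"
  else if (p <= 0.7) "+" else if (p <= 0.9) "++" else "+++"
}

.endpoint_metadata <- function() {
  path <- system.file("extdata", "endpoint_metadata.csv",
                      package = "admetkit")
  if (!nzchar(path)) return(NULL)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Systematic ADMET profile of one molecule
#'
#' Runs every registered endpoint model on the molecule and renders one row
#' per endpoint: regression endpoints report the predicted value with its
#' unit; classification endpoints report the probability and its +/-
#' symbol. Suggestion and reference texts come from the bundled endpoint
#' metadata table. A model whose features cannot be computed or matched
#' flags its row `FAILED` instead of aborting the profile.
#'
#' @param record A washed [molecule_record()].
#' @param registry Named list (endpoint name -> entry); each entry is a
#'   list with `model` (a `trained_model` or `consensus_model`) and
#'   `features` (a fingerprint kind, a descriptor family vector, or a
#'   function of a record list returning a [feature_matrix]).
#' @return An `admet_profile` data.frame: endpoint, task, value,
#'   probability, symbol, unit, suggestion, reference, status.
#' @export
systematic_profile <- function(record, registry) {
  stopifnot(inherits(record, "molecule_record"), length(registry) > 0)
  meta <- .endpoint_metadata()
  rows <- lapply(names(registry), function(ep) {
    entry <- registry[[ep]]
    row <- data.frame(endpoint = ep, task = NA_character_,
                      value = NA_real_, probability = NA_real_,
                      symbol = NA_character_, unit = NA_character_,
                      suggestion = NA_character_,
                      reference = NA_character_, status = "OK",
                      stringsAsFactors = FALSE)
    pred <- tryCatch({
      fm <- if (is.function(entry$features)) entry$features(list(record))
      else if (is.character(entry$features) &&
               entry$features[1] %in% names(FP_WIDTHS))
        compute_fingerprints(list(record), entry$features[1])
      else compute_descriptors(list(record), entry$features)
      predict(entry$model, fm_select(fm, entry$model$feature_names))
    }, error = function(e) NULL)
    if (is.null(pred)) {
      row$status <- "FAILED"
    } else if (is.data.frame(pred)) {
      row$task <- "classification"
      row$probability <- pred$probability[1]
      row$symbol <- probability_symbol(pred$probability[1])
    } else {
      row$task <- "regression"
      row$value <- pred[1]
    }
    if (!is.null(meta) && ep %in% meta$endpoint) {
      m <- meta[meta$endpoint == ep, ][1, ]
      row$unit <- m$unit
      row$suggestion <- m$suggestion
      row$reference <- m$reference
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("admet_profile", "data.frame")
  out
}
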