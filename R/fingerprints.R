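# Hashed fingerprints over the internal molecular graph.
#
# - ecfp2/4/6: extended-connectivity (Morgan) substructure identifiers with
#   circular radius 1/2/3, folded to 2048 bits.
# - fp2: linear-path fingerprint indexing fragments of up to 7 atoms, folded
#   to 2048 bits. Path identifiers are defined by this package's enumeration
#   (the layout, not any external bit ordering, is the contract).
# - maccs: the 166 MACCS structural keys (167-bit layout, bit 0 unused),
#   computed by Open Babel.

FP_WIDTHS <- c(fp2 = 2048L, maccs = 167L, ecfp2 = 2048L, ecfp4 = 2048L,
               ecfp6 = 2048L)

# Deterministic polynomial hash of a non-negative integer vector onto
# [0, 2^31 - 2]. Doubles stay below 2^53 so arithmetic is exact.
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (x + 7)) %% 2147483647
  h
}

# Unfolded ECFP substructure identifiers at the given radius. Identifiers
# from all iterations 0..radius are pooled, so the identifier set at radius
# r is a subset of the set at radius r + 1 by construction.
ecfp_identifiers <- function(graph, radius) {
  n <- graph$n_heavy
  if (n == 0) return(numeric(0))
  adj <- graph_adjacency(graph)
  ring <- graph_ring_atoms(graph)
  deg <- vapply(adj, nrow, integer(1))
  z <- ATOMIC_NUMBER[graph$elements]
  z[is.na(z)] <- 0
  ids <- vapply(seq_len(n), function(i)
    .hash_ints(c(z[i], deg[i], graph$charge[i] + 8, graph$nH[i],
                 as.integer(ring[i]))), numeric(1))
  all_ids <- ids
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_ids <- numeric(n)
      for (i in seq_len(n)) {
        nb <- adj[[i]]
        if (nrow(nb) == 0) {
          new_ids[i] <- .hash_ints(c(r, ids[i]))
        } else {
          key <- cbind(nb$order, ids[nb$nbr])
          key <- key[order(key[, 1], key[, 2]), , drop = FALSE]
          new_ids[i] <- .hash_ints(c(r, ids[i], as.numeric(t(key))))
        }
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  unique(all_ids)
}

.fold_bits <- function(ids, width) {
  row <- integer(width)
  if (length(ids) > 0) row[(ids %% width) + 1L] <- 1L
  row
}

ecfp_bits <- function(graph, radius, width = 2048L) {
  .fold_bits(ecfp_identifiers(graph, radius), width)
}

# All simple linear paths of 1..max_atoms heavy atoms, as hashed identifiers.
# Each path is read in its lexicographically smaller direction so both
# traversals map to one identifier.
fp2_identifiers <- function(graph, max_atoms = 7L) {
  n <- graph$n_heavy
  if (n == 0) return(numeric(0))
  adj <- graph_adjacency(graph)
  z <- ATOMIC_NUMBER[graph$elements]
  z[is.na(z)] <- 0
  ids <- new.env()
  emit <- function(atoms, orders) {
    fwd <- numeric(0)
    for (k in seq_along(atoms)) {
      fwd <- c(fwd, z[atoms[k]])
      if (k < length(atoms)) fwd <- c(fwd, orders[k])
    }
    m <- length(fwd)
    rev_seq <- fwd[m:1]
    key <- if (paste(fwd, collapse = ",") <= paste(rev_seq, collapse = ","))
      fwd else rev_seq
    ids[[paste(key, collapse = ",")]] <- .hash_ints(key)
  }
  walk <- function(atoms, orders) {
    emit(atoms, orders)
    if (length(atoms) == max_atoms) return()
    tip <- atoms[length(atoms)]
    nb <- adj[[tip]]
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$nbr[k]
      if (nxt %in% atoms) next
      walk(c(atoms, nxt), c(orders, nb$order[k]))
    }
  }
  for (a in seq_len(n)) walk(a, integer(0))
  unique(unlist(as.list(ids), use.names = FALSE))
}

fp2_bits <- function(graph, width = 2048L) {
  .fold_bits(fp2_identifiers(graph), width)
}

#' Compute molecular fingerprints
#'
#' Builds the bit-matrix [feature_matrix] for one of the five supported
#' fingerprint kinds: `fp2` (linear paths up to 7 atoms, 2048 bits), `maccs`
#' (166 structural keys, 167-bit layout), and `ecfp2`/`ecfp4`/`ecfp6`
#' (extended-connectivity with circular radius 1/2/3, 2048 bits each).
#'
#' @param records List of washed [molecule_record()]s.
#' @param kind One of `"fp2"`, `"maccs"`, `"ecfp2"`, `"ecfp4"`, `"ecfp6"`.
#' @return A [feature_matrix] with `kind = "fingerprint"`, one row per
#'   record (row names are record ids) and values in \{0, 1\}.
#' @examples
#' r <- molecule_record("c1ccccc1O", id = "phenol")
#' fm <- compute_fingerprints(list(r), "maccs")
#' ncol(fm)
#' @export
compute_fingerprints <- function(records,
                                 kind = c("fp2", "maccs", "ecfp2", "ecfp4",
                                          "ecfp6")) {
  kind <- match.arg(kind)
  stopifnot(length(records) > 0)
  ids <- vapply(records, `[[`, character(1), "id")
  width <- FP_WIDTHS[[kind]]
  if (kind == "maccs") {
    vals <- ob_maccs(vapply(records, `[[`, character(1), "smiles"))
  } else {
    radius <- switch(kind, ecfp2 = 1L, ecfp4 = 2L, ecfp6 = 3L, fp2 = NA)
    rows <- lapply(records, function(r) {
      if (kind == "fp2") fp2_bits(r$structure, width) else
        ecfp_bits(r$structure, radius, width)
    })
    vals <- do.call(rbind, rows)
    colnames(vals) <- paste0(kind, "_", seq_len(width) - 1L)
  }
  rownames(vals) <- ids
  feature_matrix(vals, kind = "fingerprint",
                 family = setNames(rep(kind, width), colnames(vals)))
}
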