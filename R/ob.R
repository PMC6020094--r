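# Thin wrappers around Open Babel (via ChemmineOB). All structure parsing and
# canonical SMILES generation go through here; everything downstream works on
# the internal graph representation in mol-graph.R.

# Convert one molecule between text formats. Returns NA_character_ when Open
# Babel cannot parse the input (it emits an empty string in that case).
ob_convert <- function(text, from, to, explicit_h = FALSE) {
  opts <- if (explicit_h) data.frame(names = "h", args = "") else
    data.frame(names = character(), args = character())
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, text, options = opts),
    error = function(e) ""
  )
  if (!nzchar(trimws(out))) NA_character_ else out
}

# Canonical SMILES for a vector of SMILES strings; NA where unparseable.
# Open Babel's "CAN" writer emits "smiles\ttitle"; the title is dropped.
ob_canonical <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ob_convert(paste0(s, "\n"), "SMI", "CAN")
    if (is.na(out)) return(NA_character_)
    first <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
    strsplit(first, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

# One SDF (V2000) block for a single SMILES, optionally with explicit
# hydrogens added by Open Babel. NA when unparseable.
ob_sdf_block <- function(smiles, explicit_h = TRUE) {
  ob_convert(paste0(smiles, "\n"), "SMI", "SDF", explicit_h = explicit_h)
}

# Canonical SMILES from an SDF/molblock text.
ob_sdf_to_smiles <- function(sdf_text) {
  out <- ob_convert(sdf_text, "SDF", "CAN")
  if (is.na(out)) return(NA_character_)
  strsplit(strsplit(out, "\n", fixed = TRUE)[[1]][1], "\t", fixed = TRUE)[[1]][1]
}

# OBMol references for a vector of (already validated) SMILES.
ob_mols <- function(smiles) {
  txt <- paste0(paste(smiles, seq_along(smiles)), collapse = "\n")
  ChemmineOB::forEachMol("SMI", txt, identity)
}

# Open Babel property block (logP, MR, TPSA, HBD, HBA1/2, MW, ...) for a
# vector of valid SMILES. One row per molecule, in input order.
ob_properties <- function(smiles) {
  ChemmineOB::prop_OB(ob_mols(smiles))
}

# MACCS keys (166 structural keys) from Open Babel, reported as a 167-bit
# matrix in the conventional layout: column k+1 holds key k, bit 0 unused.
ob_maccs <- function(smiles) {
  raw <- ChemmineOB::fingerprint_OB(ob_mols(smiles), "MACCS")
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  out <- matrix(0L, nrow = length(smiles), ncol = 167)
  keys <- min(166L, ncol(raw))
  out[, seq_len(keys) + 1L] <- (raw[, seq_len(keys), drop = FALSE] != 0) * 1L
  colnames(out) <- paste0("maccs_", 0:166)
  out
}

# Number of unique SMARTS matches per molecule.
ob_smarts_count <- function(smiles, smarts) {
  as.integer(ChemmineOB::smartsSearch_OB(ob_mols(smiles), smarts,
                                         uniqueMatches = TRUE))
}
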