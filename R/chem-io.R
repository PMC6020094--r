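#' Molecule records
#'
#' A `molecule_record` holds one parsed molecule: a unique `id`, the
#' canonical SMILES, an optional name, the parsed structure (an internal
#' heavy-atom graph), and the 0-based position in the input it came from.
#'
#' @param smiles A SMILES string.
#' @param id Unique identifier. Defaults to the SMILES itself.
#' @param name Optional human-readable name.
#' @param source_index 0-based input position.
#' @return A `molecule_record`, or `NULL` when the SMILES cannot be parsed.
#' @examples
#' r <- molecule_record("CCO", id = "ethanol")
#' r$smiles
#' @export
molecule_record <- function(smiles, id = smiles, name = NULL,
                            source_index = 0L) {
  can <- ob_canonical(smiles)
  if (is.na(can)) return(NULL)
  block <- ob_sdf_block(can, explicit_h = TRUE)
  if (is.na(block)) return(NULL)
  structure(list(id = as.character(id), smiles = can, name = name,
                 structure = parse_molblock(block),
                 source_index = as.integer(source_index)),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record %s: %s (%d heavy atoms)>\n",
              x$id, x$smiles, x$structure$n_heavy))
  invisible(x)
}

wash_report <- function(input_count, parsed_count, washed_count, removals) {
  structure(list(input_count = input_count, parsed_count = parsed_count,
                 washed_count = washed_count, removals = removals),
            class = "wash_report")
}

#' @export
print.wash_report <- function(x, ...) {
  cat(sprintf("<wash_report: %d in, %d parsed, %d kept, %d issue(s)>\n",
              x$input_count, x$parsed_count, x$washed_count,
              nrow(x$removals)))
  invisible(x)
}

.empty_removals <- function() {
  data.frame(id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

.dedup_ids <- function(ids) {
  removals <- .empty_removals()
  seen <- table(character())
  out <- ids
  counts <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (is.null(counts[[id]])) {
      counts[[id]] <- 1L
    } else {
      counts[[id]] <- counts[[id]] + 1L
      out[i] <- paste0(id, "_", counts[[id]])
      removals <- rbind(removals,
                        data.frame(id = id, reason = "DUPLICATE_ID"))
    }
  }
  list(ids = out, removals = removals)
}

#' Read molecules from SMILES, SDF or CSV files
#'
#' Reads one of the three accepted input formats into a list of
#' [molecule_record()]s plus a report of entries that could not be used.
#' Unparseable entries are logged with reason `UNPARSEABLE`, never silently
#' dropped; duplicated identifiers are made unique with an ordinal suffix and
#' logged as `DUPLICATE_ID`.
#'
#' * `smi`: one molecule per line, `SMILES[ whitespace name]`; lines starting
#'   with `#` are comments.
#' * `sdf`: a V2000 SD file; the molecule title supplies the id.
#' * `csv`: comma-separated with a header; requires a `smiles` column, an
#'   `id` column is optional (row index used if absent), other columns are
#'   carried through as a `properties` attribute.
#'
#' @param path Input file path.
#' @param format One of `"smi"`, `"sdf"`, `"csv"`.
#' @return A list with `records` (list of `molecule_record`) and `report`
#'   (a `wash_report` whose removals log parse failures and duplicate ids).
#' @export
read_molecules <- function(path, format = c("smi", "sdf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  entries <- switch(format,
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- trimws(sub("#.*$", "", lines))
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "[[:space:]]+")
      data.frame(
        smiles = vapply(parts, `[`, character(1), 1),
        name = vapply(parts, function(p)
          if (length(p) > 1) paste(p[-1], collapse = " ") else
            NA_character_, character(1)),
        stringsAsFactors = FALSE)
    },
    csv = {
      tab <- read.csv(path, stringsAsFactors = FALSE)
      if (!"smiles" %in% names(tab))
        stop("CSV input must contain a 'smiles' column")
      out <- data.frame(
        smiles = as.character(tab$smiles),
        name = if ("id" %in% names(tab)) as.character(tab$id) else
          NA_character_,
        stringsAsFactors = FALSE)
      extras <- setdiff(names(tab), c("id", "smiles"))
      attr(out, "properties") <- tab[, extras, drop = FALSE]
      out
    },
    sdf = {
      txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
      blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
      blocks <- blocks[nzchar(trimws(blocks))]
      data.frame(
        smiles = vapply(blocks, function(b)
          ob_sdf_to_smiles(paste0(b, "\n$$$$\n")), character(1),
          USE.NAMES = FALSE),
        name = vapply(blocks, function(b)
          trimws(strsplit(b, "\n")[[1]][1]), character(1),
          USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    })

  n_in <- nrow(entries)
  if (n_in == 0) stop("empty input: no molecules in ", path)
  ids <- ifelse(is.na(entries$name) | !nzchar(entries$name),
                sprintf("mol_%04d", seq_len(n_in)), entries$name)
  fix <- .dedup_ids(ids)
  removals <- fix$removals

  records <- list()
  parsed <- 0L
  for (i in seq_len(n_in)) {
    smi <- entries$smiles[i]
    rec <- if (is.na(smi)) NULL else
      molecule_record(smi, id = fix$ids[i],
                      name = if (is.na(entries$name[i])) NULL else
                        entries$name[i],
                      source_index = i - 1L)
    props <- attr(entries, "properties")
    if (!is.null(rec) && !is.null(props) && ncol(props) > 0)
      rec$properties <- as.list(props[i, , drop = FALSE])
    if (is.null(rec)) {
      removals <- rbind(removals,
                        data.frame(id = fix$ids[i], reason = "UNPARSEABLE"))
    } else {
      parsed <- parsed + 1L
      records[[length(records) + 1L]] <- rec
    }
  }
  if (parsed == 0L) stop("empty input: no parseable molecules in ", path)
  list(records = records,
       report = wash_report(n_in, parsed, parsed, removals))
}

#' Canonicalize a SMILES string
#'
#' Maps any SMILES spelling of a molecular graph to a single canonical form
#' (idempotent: canonicalizing a canonical SMILES returns it unchanged).
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES.
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' @export
canonicalize <- function(smiles) {
  out <- ob_canonical(smiles)
  if (is.na(out)) stop("cannot parse SMILES: '", smiles, "'")
  out
}

#' Wash a molecule
#'
#' Structure standardization applied before featurization: bonds between
#' alkali/alkaline-earth metals and O/N/S are disconnected (simple salts),
#' the largest fragment by heavy-atom count is kept, and hydrogens are made
#' explicit on the stored structure. The stored SMILES remains in implicit-H
#' canonical form. Washing is idempotent.
#'
#' Ties in fragment size are broken by molecular weight, then by
#' lexicographically smallest canonical SMILES.
#'
#' @param record A [molecule_record()].
#' @return The washed `molecule_record`, or `NULL` if no heavy atoms remain
#'   (logged by [wash_molecules()] as `EMPTY_AFTER_WASH`).
#' @examples
#' r <- molecule_record("CCO.Cl")
#' wash_molecule(r)$smiles
#' @export
wash_molecule <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  g <- record$structure
  if (g$n_heavy == 0) return(NULL)

  # 1. disconnect metal--(O,N,S) bonds in simple salts
  b <- g$bonds
  if (nrow(b) > 0) {
    ef <- g$elements[b$from]; et <- g$elements[b$to]
    salt <- (ef %in% SALT_METALS & et %in% c("O", "N", "S")) |
            (et %in% SALT_METALS & ef %in% c("O", "N", "S"))
    # cleaving heterolytically: metal keeps +1/+2, O/N/S gains -1 per bond
    for (k in which(salt)) {
      m_is_from <- ef[k] %in% SALT_METALS
      m <- if (m_is_from) b$from[k] else b$to[k]
      x <- if (m_is_from) b$to[k] else b$from[k]
      g$charge[m] <- g$charge[m] + b$order[k]
      g$charge[x] <- g$charge[x] - b$order[k]
    }
    g$bonds <- b[!salt, , drop = FALSE]
  }

  # 2. largest fragment by heavy atoms, ties by MW then canonical SMILES
  comp <- igraph::components(graph_as_igraph(g))$membership
  frags <- split(seq_len(g$n_heavy), comp)
  sizes <- lengths(frags)
  cand <- frags[sizes == max(sizes)]
  if (length(cand) > 1) {
    mws <- vapply(cand, function(a) graph_mw(g, a), numeric(1))
    cand <- cand[abs(mws - max(mws)) < 1e-9]
  }
  if (length(cand) > 1) {
    smis <- vapply(cand, function(a)
      ob_sdf_to_smiles(graph_to_molblock(g, a)), character(1))
    cand <- cand[order(smis)][1]
  }
  keep <- cand[[1]]

  smi <- ob_sdf_to_smiles(graph_to_molblock(g, keep, title = record$id))
  if (is.na(smi)) return(NULL)
  out <- molecule_record(smi, id = record$id, name = record$name,
                         source_index = record$source_index)
  out
}

#' Wash a list of molecule records
#'
#' Applies [wash_molecule()] to every record, collecting removals
#' (`EMPTY_AFTER_WASH`) into a [wash_report].
#'
#' @param records List of [molecule_record()]s.
#' @param report Optional upstream `wash_report` (from [read_molecules()])
#'   whose counts and removal log are extended.
#' @return A list with `records` and `report`.
#' @export
wash_molecules <- function(records, report = NULL) {
  removals <- if (is.null(report)) .empty_removals() else report$removals
  input_count <- if (is.null(report)) length(records) else report$input_count
  parsed_count <- if (is.null(report)) length(records) else
    report$parsed_count
  out <- list()
  for (rec in records) {
    w <- wash_molecule(rec)
    if (is.null(w)) {
      removals <- rbind(removals,
                        data.frame(id = rec$id, reason = "EMPTY_AFTER_WASH"))
    } else {
      out[[length(out) + 1L]] <- w
    }
  }
  list(records = out,
       report = wash_report(input_count, parsed_count, length(out),
                            removals))
}

#' Write molecules to a SMILES or SDF file
#'
#' @param records List of [molecule_record()]s.
#' @param path Output path.
#' @param format `"smi"` (SMILES + id per line) or `"sdf"` (V2000).
#' @return `path`, invisibly.
#' @export
write_molecules <- function(records, path, format = c("smi", "sdf")) {
  format <- match.arg(format)
  if (format == "smi") {
    writeLines(vapply(records, function(r) paste(r$smiles, r$id),
                      character(1)), path)
  } else {
    blocks <- vapply(records, function(r) {
      b <- ob_convert(paste(r$smiles, r$id, "\n"), "SMI", "SDF")
      if (is.na(b)) stop("cannot render SDF for ", r$id)
      b
    }, character(1))
    writeLines(paste0(blocks, collapse = ""), sep = "", con = path)
  }
  invisible(path)
}
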