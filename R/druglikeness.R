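# Drug-likeness rule batteries: Lipinski, Ghose, Oprea (lead-like), Veber
# and Varma. Thresholds follow the commonly published forms and are plain
# data, overridable through a key=value config file without code changes.

#' Physicochemical descriptors used by the drug-likeness rules
#'
#' MW, LogP, TPSA and molar refractivity come from Open Babel; hydrogen
#' bond donors/acceptors use the Lipinski conventions (HBA = N + O count,
#' HBD = N/O atoms carrying at least one hydrogen); rotatable bonds are
#' non-ring single bonds between non-terminal heavy atoms; `rings` is the
#' smallest-set ring count (cyclomatic number); `atoms` counts all atoms
#' including hydrogens.
#'
#' @param records List of washed [molecule_record()]s.
#' @return A data.frame with one row per record (rownames = ids) and
#'   columns MW, LogP, TPSA, MR, HBA, HBD, RotB, rings, atoms.
#' @export
rule_descriptors <- function(records) {
  smiles <- vapply(records, `[[`, character(1), "smiles")
  props <- ob_properties(smiles)
  rotb <- ob_smarts_count(smiles, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  per_graph <- t(vapply(records, function(r) {
    g <- r$structure
    no <- g$elements %in% c("N", "O")
    c(HBA = sum(no),
      HBD = sum(no & g$nH > 0),
      rings = nrow(g$bonds) - g$n_heavy +
        igraph::components(graph_as_igraph(g))$no,
      atoms = g$n_heavy + sum(g$nH))
  }, numeric(4)))
  out <- data.frame(MW = props$MW, LogP = props$logP, TPSA = props$TPSA,
                    MR = props$MR, per_graph, RotB = rotb)
  rownames(out) <- vapply(records, `[[`, character(1), "id")
  out
}

.criterion <- function(descriptor, comparator, lo = NA, hi = NA) {
  list(descriptor = descriptor, comparator = comparator, lo = lo, hi = hi)
}

#' The five drug-likeness rule definitions
#'
#' Each rule is a list of criteria over [rule_descriptors()] columns with a
#' `max_violations` allowance (1 for Lipinski, otherwise 0):
#' * lipinski: MW <= 500, LogP <= 5, HBD <= 5, HBA <= 10
#' * ghose: 160 <= MW <= 480, -0.4 <= LogP <= 5.6, 40 <= MR <= 130,
#'   20 <= atoms <= 70
#' * oprea (lead-like): MW <= 450, LogP <= 4.5, rings <= 4, RotB <= 10,
#'   HBD <= 5, HBA <= 8
#' * veber: RotB <= 10, TPSA <= 140
#' * varma: MW <= 500, TPSA <= 125, LogP <= 5 (as a logD proxy)
#'
#' @return Named list of rule definitions.
#' @export
default_rules <- function() {
  list(
    lipinski = list(name = "lipinski", max_violations = 1L, criteria = list(
      .criterion("MW", "le", hi = 500),
      .criterion("LogP", "le", hi = 5),
      .criterion("HBD", "le", hi = 5),
      .criterion("HBA", "le", hi = 10))),
    ghose = list(name = "ghose", max_violations = 0L, criteria = list(
      .criterion("MW", "range", 160, 480),
      .criterion("LogP", "range", -0.4, 5.6),
      .criterion("MR", "range", 40, 130),
      .criterion("atoms", "range", 20, 70))),
    oprea = list(name = "oprea", max_violations = 0L, criteria = list(
      .criterion("MW", "le", hi = 450),
      .criterion("LogP", "le", hi = 4.5),
      .criterion("rings", "le", hi = 4),
      .criterion("RotB", "le", hi = 10),
      .criterion("HBD", "le", hi = 5),
      .criterion("HBA", "le", hi = 8))),
    veber = list(name = "veber", max_violations = 0L, criteria = list(
      .criterion("RotB", "le", hi = 10),
      .criterion("TPSA", "le", hi = 140))),
    varma = list(name = "varma", max_violations = 0L, criteria = list(
      .criterion("MW", "le", hi = 500),
      .criterion("TPSA", "le", hi = 125),
      .criterion("LogP", "le", hi = 5))))
}

.criterion_pass <- function(crit, value) {
  switch(crit$comparator,
         le = value <= crit$hi,
         ge = value >= crit$lo,
         range = value >= crit$lo & value <= crit$hi,
         stop("unknown comparator: ", crit$comparator))
}

.criterion_bound <- function(crit) {
  switch(crit$comparator,
         le = paste0("<= ", crit$hi),
         ge = paste0(">= ", crit$lo),
         range = paste0("[", crit$lo, ", ", crit$hi, "]"))
}

#' Evaluate one drug-likeness rule for one molecule
#'
#' Every criterion is evaluated and reported (no short-circuiting); the
#' molecule passes when the number of violations does not exceed the
#' rule's allowance.
#'
#' @param record A washed [molecule_record()], or a named numeric vector /
#'   one-row data.frame of pre-computed [rule_descriptors()].
#' @param rule One entry of [default_rules()].
#' @return A `rule_result`: list with `id`, `rule`, `criteria` (data.frame
#'   of descriptor, value, bound, pass), `n_violations`, `overall_pass`.
#' @export
evaluate_rule <- function(record, rule) {
  if (inherits(record, "molecule_record")) {
    desc <- rule_descriptors(list(record))
    id <- record$id
  } else if (is.data.frame(record)) {
    desc <- record
    id <- attr(record, "id") %||% rownames(record)[1]
  } else {
    desc <- as.data.frame(as.list(record))
    id <- attr(record, "id") %||% "molecule"
  }
  crits <- lapply(rule$criteria, function(cr) {
    val <- desc[[cr$descriptor]][1]
    data.frame(descriptor = cr$descriptor, value = val,
               bound = .criterion_bound(cr),
               pass = .criterion_pass(cr, val))
  })
  tab <- do.call(rbind, crits)
  nv <- sum(!tab$pass)
  structure(list(id = id, rule = rule$name, criteria = tab,
                 n_violations = nv,
                 overall_pass = nv <= rule$max_violations),
            class = "rule_result")
}

#' Screen molecules against all five drug-likeness rules
#'
#' @param records List of [molecule_record()]s (may be empty).
#' @param rules Rule list (default [default_rules()]).
#' @return A data.frame with one row per molecule x rule: `id`, `rule`,
#'   `n_violations`, `overall_pass`, `status` (`OK` or `INCOMPUTABLE`).
#' @export
evaluate_all <- function(records, rules = default_rules()) {
  rows <- list()
  for (rec in records) {
    desc <- tryCatch(rule_descriptors(list(rec)), error = function(e) NULL)
    for (rule in rules) {
      if (is.null(desc) || any(!is.finite(unlist(desc)))) {
        rows[[length(rows) + 1L]] <-
          data.frame(id = rec$id, rule = rule$name,
                     n_violations = NA_integer_, overall_pass = NA,
                     status = "INCOMPUTABLE")
      } else {
        d <- desc[1, ]
        attr(d, "id") <- rec$id
        res <- evaluate_rule(d, rule)
        rows[[length(rows) + 1L]] <-
          data.frame(id = rec$id, rule = rule$name,
                     n_violations = res$n_violations,
                     overall_pass = res$overall_pass, status = "OK")
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(id = character(), rule = character(),
                      n_violations = integer(), overall_pass = logical(),
                      status = character()))
  do.call(rbind, rows)
}

#' Override rule thresholds from a plain-text config file
#'
#' Lines of the form `rule.descriptor = value` (single bound) or
#' `rule.descriptor = lo:hi` (range), e.g. `lipinski.MW = 550`. Unknown
#' rules or descriptors raise an error.
#'
#' @param rules Rule list to modify.
#' @param path Config file path.
#' @return The modified rule list.
#' @export
apply_rule_config <- function(rules, path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("config keys are rule.descriptor: '",
                                 key, "'")
    rn <- parts[1]; dn <- parts[2]
    if (!rn %in% names(rules)) stop("unknown rule: '", rn, "'")
    hit <- FALSE
    for (i in seq_along(rules[[rn]]$criteria)) {
      cr <- rules[[rn]]$criteria[[i]]
      if (cr$descriptor == dn) {
        if (grepl(":", val, fixed = TRUE)) {
          b <- as.numeric(strsplit(val, ":", fixed = TRUE)[[1]])
          cr$lo <- b[1]; cr$hi <- b[2]; cr$comparator <- "range"
        } else if (cr$comparator == "ge") {
          cr$lo <- as.numeric(val)
        } else {
          cr$hi <- as.numeric(val)
        }
        rules[[rn]]$criteria[[i]] <- cr
        hit <- TRUE
      }
    }
    if (!hit) stop("rule '", rn, "' has no criterion on '", dn, "'")
  }
  rules
}
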