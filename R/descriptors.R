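# Two-dimensional molecular descriptors, organised in the classical family
# groupings (constitutional, topological, connectivity, E-state, kappa shape,
# Basak information content, Burden eigenvalues, autocorrelation, charge,
# molecular property, MOE-type). Family membership is the contract; the
# per-family counts are documented in descriptor_manifest().

VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4,
                       P = 5, S = 6, Cl = 7, Br = 7, I = 7)
QUANTUM_ROW <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3,
                 S = 3, Cl = 3, Br = 4, I = 5)
# Kier covalent-radius alpha contributions (relative to sp3 carbon).
KIER_RADII <- c(C = 0.77, N = 0.74, O = 0.74, F = 0.72, P = 1.10, S = 1.04,
                Cl = 0.99, Br = 1.14, I = 1.33, B = 0.82, Si = 1.17)

.deg <- function(g) {
  d <- integer(g$n_heavy)
  for (k in seq_len(nrow(g$bonds))) {
    d[g$bonds$from[k]] <- d[g$bonds$from[k]] + 1L
    d[g$bonds$to[k]] <- d[g$bonds$to[k]] + 1L
  }
  d
}

# Kier-Hall valence delta.
.delta_v <- function(g) {
  z <- ATOMIC_NUMBER[g$elements]
  zv <- VALENCE_ELECTRONS[g$elements]
  zv[is.na(zv)] <- 1
  z[is.na(z)] <- 1
  dv <- (zv - g$nH) / pmax(z - zv - 1, 1)
  dv[QUANTUM_ROW[g$elements] %in% c(NA, 1, 2)] <-
    (zv - g$nH)[QUANTUM_ROW[g$elements] %in% c(NA, 1, 2)]
  pmax(dv, 0.001)
}

# Count of simple paths with exactly k edges (each path counted once).
.path_counts <- function(g, kmax = 3L) {
  adj <- graph_adjacency(g)
  counts <- numeric(kmax)
  walk <- function(atoms, depth) {
    if (depth > 0) counts[depth] <<- counts[depth] + 1
    if (depth == kmax) return()
    nb <- adj[[atoms[length(atoms)]]]
    for (k in seq_len(nrow(nb)))
      if (!(nb$nbr[k] %in% atoms)) walk(c(atoms, nb$nbr[k]), depth + 1L)
  }
  for (a in seq_len(g$n_heavy)) walk(a, 0L)
  counts / 2
}

# Simple paths as atom index lists, by edge count (for chi indices).
.paths_by_order <- function(g, kmax = 4L) {
  adj <- graph_adjacency(g)
  paths <- rep(list(list()), kmax)
  walk <- function(atoms, depth) {
    if (depth > 0) {
      first <- atoms[1]; last <- atoms[length(atoms)]
      if (first < last)  # each undirected path once
        paths[[depth]][[length(paths[[depth]]) + 1L]] <<- atoms
    }
    if (depth == kmax) return()
    nb <- adj[[atoms[length(atoms)]]]
    for (k in seq_len(nrow(nb)))
      if (!(nb$nbr[k] %in% atoms)) walk(c(atoms, nb$nbr[k]), depth + 1L)
  }
  for (a in seq_len(g$n_heavy)) walk(a, 0L)
  paths
}

desc_constitution <- function(g) {
  el <- g$elements
  b <- g$bonds
  nhal <- sum(el %in% c("F", "Cl", "Br", "I"))
  c(nheavy = g$n_heavy,
    nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nS = sum(el == "S"), nP = sum(el == "P"), nF = sum(el == "F"),
    nCl = sum(el == "Cl"), nBr = sum(el == "Br"), nI = sum(el == "I"),
    nHal = nhal, nHet = sum(!el %in% c("C", "H")),
    nH = sum(g$nH),
    nBond = nrow(b),
    nSingle = sum(b$order == 1), nDouble = sum(b$order == 2),
    nTriple = sum(b$order == 3),
    nRing = nrow(b) - g$n_heavy +
      igraph::components(graph_as_igraph(g))$no,
    MW = graph_mw(g),
    AMW = graph_mw(g) / max(1, g$n_heavy + sum(g$nH)))
}

desc_topology <- function(g) {
  dm <- graph_distances(g)
  fin <- is.finite(dm) & dm > 0
  dvec <- dm[fin & upper.tri(dm)]
  deg <- .deg(g)
  b <- g$bonds
  wiener <- sum(dvec)
  harary <- sum(1 / dvec)
  ecc <- apply(ifelse(is.finite(dm), dm, 0), 1, max)
  mu <- nrow(b) - g$n_heavy + igraph::components(graph_as_igraph(g))$no
  s <- rowSums(ifelse(is.finite(dm), dm, 0))
  balaban <- if (nrow(b) > 0 && all(s[c(b$from, b$to)] > 0))
    nrow(b) / (mu + 1) * sum(1 / sqrt(s[b$from] * s[b$to])) else 0
  c(Wiener = wiener,
    MeanWiener = if (length(dvec)) mean(dvec) else 0,
    Harary = harary,
    Zagreb1 = sum(deg^2),
    Zagreb2 = if (nrow(b)) sum(deg[b$from] * deg[b$to]) else 0,
    Platt = if (nrow(b)) sum(deg[b$from] + deg[b$to] - 2) else 0,
    BalabanJ = balaban,
    Radius = if (g$n_heavy) min(ecc) else 0,
    Diameter = if (g$n_heavy) max(ecc) else 0,
    EccConn = sum(deg * ecc))
}

desc_connectivity <- function(g) {
  deg <- pmax(.deg(g), 1e-8)
  dv <- .delta_v(g)
  paths <- .paths_by_order(g, 4L)
  chi <- function(delta) {
    out <- numeric(5)
    out[1] <- sum(1 / sqrt(delta))
    for (m in 1:4) {
      ps <- paths[[m]]
      out[m + 1] <- if (length(ps))
        sum(vapply(ps, function(p) 1 / sqrt(prod(delta[p])), numeric(1)))
      else 0
    }
    out
  }
  s <- chi(deg); v <- chi(dv)
  setNames(c(s, v),
           c(paste0("Chi", 0:4), paste0("Chiv", 0:4)))
}

desc_kappa <- function(g) {
  A <- g$n_heavy
  p <- .path_counts(g, 3L)
  alpha <- sum((KIER_RADII[g$elements] / 0.77 - 1), na.rm = TRUE)
  k1 <- function(a, p1) if (p1 > 0) (a) * (a - 1)^2 / p1^2 else 0
  k2 <- function(a, p2) if (p2 > 0) (a - 1) * (a - 2)^2 / p2^2 else 0
  k3 <- function(a, p3) {
    if (p3 <= 0) return(0)
    if (a %% 2 == 1) (a - 1) * (a - 3)^2 / p3^2 else
      (a - 3) * (a - 2)^2 / p3^2
  }
  kap1 <- k1(A, p[1]); kap2 <- k2(A, p[2]); kap3 <- k3(A, p[3])
  ka1 <- k1(A + alpha, p[1] + alpha)
  ka2 <- k2(A + alpha, p[2] + alpha)
  ka3 <- k3(A + alpha, p[3] + alpha)
  phi <- if (A > 0) ka1 * ka2 / A else 0
  c(Kappa1 = kap1, Kappa2 = kap2, Kappa3 = kap3,
    KappaA1 = ka1, KappaA2 = ka2, KappaA3 = ka3, Phi = phi)
}

desc_estate <- function(g) {
  if (g$n_heavy == 0)
    return(c(SSum = 0, SMax = 0, SMin = 0, SMean = 0, SPos = 0, SNeg = 0,
             SHet = 0, SHal = 0))
  deg <- pmax(.deg(g), 1)
  dv <- .delta_v(g)
  L <- QUANTUM_ROW[g$elements]
  L[is.na(L)] <- 4
  I <- ((2 / L)^2 * dv + 1) / deg
  dm <- graph_distances(g) + 1
  S <- I
  for (i in seq_len(g$n_heavy)) {
    dI <- (I[i] - I) / dm[i, ]^2
    dI[!is.finite(dI)] <- 0
    S[i] <- I[i] + sum(dI[-i])
  }
  het <- !g$elements %in% "C"
  hal <- g$elements %in% c("F", "Cl", "Br", "I")
  c(SSum = sum(S), SMax = max(S), SMin = min(S), SMean = mean(S),
    SPos = sum(S[S > 0]), SNeg = sum(S[S < 0]),
    SHet = sum(S[het]), SHal = sum(S[hal]))
}

# Shannon information content over atom equivalence classes. Hydrogens are
# included as atoms of their own element class.
desc_basak <- function(g) {
  els <- c(g$elements, rep("H", sum(g$nH)))
  n <- length(els)
  ic <- function(classes) {
    p <- table(classes) / length(classes)
    -sum(p * log2(p))
  }
  # order 0: element identity; order 1: element + neighbour element multiset
  adj <- graph_adjacency(g)
  cls1_heavy <- vapply(seq_len(g$n_heavy), function(i) {
    nbrs <- sort(c(g$elements[adj[[i]]$nbr], rep("H", g$nH[i])))
    paste(g$elements[i], paste(nbrs, collapse = ""), sep = ":")
  }, character(1))
  cls1_h <- unlist(lapply(seq_len(g$n_heavy), function(i)
    rep(paste("H", g$elements[i], sep = ":"), g$nH[i])))
  ic0 <- ic(els)
  ic1 <- ic(c(cls1_heavy, cls1_h))
  lg <- log2(max(2, n))
  c(IC0 = ic0, SIC0 = ic0 / lg, CIC0 = lg - ic0,
    IC1 = ic1, SIC1 = ic1 / lg, CIC1 = lg - ic1)
}

# Burden-matrix eigenvalue descriptors (BCUT-like): diagonal weighted by
# atomic mass or electronegativity, bonded off-diagonals = order / 10,
# non-bonded pairs = 0.001. Four highest and four lowest eigenvalues per
# weighting; molecules with fewer than four atoms repeat the extreme value.
desc_burden <- function(g) {
  n <- g$n_heavy
  pick <- function(ev, k = 4) {
    hi <- sort(ev, decreasing = TRUE)
    lo <- sort(ev)
    c(hi[pmin(seq_len(k), length(ev))], lo[pmin(seq_len(k), length(ev))])
  }
  if (n == 0) return(setNames(numeric(16), c(paste0("BCUTm", 1:8),
                                             paste0("BCUTe", 1:8))))
  B <- matrix(0.001, n, n)
  for (k in seq_len(nrow(g$bonds))) {
    v <- g$bonds$order[k] / 10
    B[g$bonds$from[k], g$bonds$to[k]] <- v
    B[g$bonds$to[k], g$bonds$from[k]] <- v
  }
  w_m <- ATOMIC_MASS[g$elements]; w_m[is.na(w_m)] <- 10
  w_e <- PAULING_EN[g$elements]; w_e[is.na(w_e)] <- 2
  evm <- eigen({ Bm <- B; diag(Bm) <- w_m; Bm }, symmetric = TRUE,
               only.values = TRUE)$values
  eve <- eigen({ Be <- B; diag(Be) <- w_e; Be }, symmetric = TRUE,
               only.values = TRUE)$values
  setNames(c(pick(evm), pick(eve)),
           c(paste0("BCUTm", 1:8), paste0("BCUTe", 1:8)))
}

# Moreau-Broto autocorrelation at topological lags 1..8 on atomic mass and
# Pauling electronegativity (lags beyond the diameter are 0).
desc_autocorrelation <- function(g) {
  dm <- graph_distances(g)
  w_m <- ATOMIC_MASS[g$elements]; w_m[is.na(w_m)] <- 10
  w_e <- PAULING_EN[g$elements]; w_e[is.na(w_e)] <- 2
  ats <- function(w) {
    vapply(1:8, function(d) {
      sel <- which(dm == d & upper.tri(dm), arr.ind = TRUE)
      if (nrow(sel) == 0) 0 else sum(w[sel[, 1]] * w[sel[, 2]])
    }, numeric(1))
  }
  setNames(c(ats(w_m), ats(w_e)),
           c(paste0("ATSm", 1:8), paste0("ATSe", 1:8)))
}

# Electronegativity-difference partial-charge proxies plus formal-charge
# counts. The per-atom charge is the bond-order-weighted sum of normalized
# electronegativity differences to bonded neighbours.
desc_charge <- function(g) {
  en <- PAULING_EN[g$elements]; en[is.na(en)] <- 2
  q <- as.numeric(g$charge)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$from[k]; j <- g$bonds$to[k]
    d <- g$bonds$order[k] * (en[j] - en[i]) / (en[i] + en[j])
    q[i] <- q[i] + d
    q[j] <- q[j] - d
  }
  c(QMaxPos = if (any(q > 0)) max(q) else 0,
    QMaxNeg = if (any(q < 0)) min(q) else 0,
    QTotPos = sum(q[q > 0]), QTotNeg = sum(q[q < 0]),
    QMeanAbs = if (length(q)) mean(abs(q)) else 0,
    QNet = sum(g$charge),
    nFormalPos = sum(g$charge > 0), nFormalNeg = sum(g$charge < 0))
}

#' Names of the descriptor families
#' @export
DESCRIPTOR_FAMILIES <- c("constitution", "topology", "connectivity",
                         "estate", "kappa", "basak", "burden",
                         "autocorrelation", "charge", "property", "moe_type")

# Families computed from Open Babel properties / SMARTS rather than the
# internal graph (vectorized across the record list).
.ob_family_block <- function(records, family) {
  smiles <- vapply(records, `[[`, character(1), "smiles")
  props <- ob_properties(smiles)
  if (family == "property") {
    cbind(MW = props$MW, LogP = props$logP, TPSA = props$TPSA,
          HBA = props$HBA2, HBD = props$HBD, MR = props$MR)
  } else {  # moe_type
    arom <- ob_smarts_count(smiles, "[a]")
    rotb <- ob_smarts_count(smiles, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
    cbind(TPSA = props$TPSA, SLogP = props$logP, SMR = props$MR,
          a_aro = arom, b_rotN = rotb,
          a_heavy = vapply(records, function(r) r$structure$n_heavy,
                           numeric(1)))
  }
}

#' Compute molecular descriptors
#'
#' Computes continuous 2D descriptors for the requested families, returned
#' as one [feature_matrix] with per-family column blocks in declared family
#' order. Column names carry a family prefix (e.g. `topology_Wiener`).
#' Molecules for which any requested descriptor fails are excluded from the
#' matrix and listed in the `failures` attribute.
#'
#' @param records List of washed [molecule_record()]s.
#' @param families Character vector of family names; see
#'   [descriptor_manifest()] for the catalogue. Defaults to all families.
#' @return A [feature_matrix] with `kind = "descriptor"` and an attribute
#'   `failures` (character vector of excluded molecule ids).
#' @examples
#' r <- molecule_record("CCO", id = "ethanol")
#' fm <- compute_descriptors(list(r), families = "property")
#' colnames(fm)
#' @export
compute_descriptors <- function(records, families = DESCRIPTOR_FAMILIES) {
  if (length(families) == 0) stop("at least one descriptor family required")
  families <- match.arg(families, DESCRIPTOR_FAMILIES, several.ok = TRUE)
  families <- DESCRIPTOR_FAMILIES[DESCRIPTOR_FAMILIES %in% families]
  stopifnot(length(records) > 0)
  ids <- vapply(records, `[[`, character(1), "id")

  graph_funs <- list(constitution = desc_constitution,
                     topology = desc_topology,
                     connectivity = desc_connectivity,
                     estate = desc_estate, kappa = desc_kappa,
                     basak = desc_basak, burden = desc_burden,
                     autocorrelation = desc_autocorrelation,
                     charge = desc_charge)

  blocks <- list()
  fam_tags <- character(0)
  ok <- rep(TRUE, length(records))
  for (fam in families) {
    if (fam %in% c("property", "moe_type")) {
      vals <- tryCatch(.ob_family_block(records, fam), error = function(e)
        NULL)
      if (is.null(vals)) { ok[] <- FALSE; next }
    } else {
      rows <- lapply(records, function(r)
        tryCatch(graph_funs[[fam]](r$structure), error = function(e) NULL))
      bad <- vapply(rows, is.null, logical(1))
      ok <- ok & !bad
      if (all(bad)) next
      rows[bad] <- list(rows[[which(!bad)[1]]] * NA)
      vals <- do.call(rbind, rows)
    }
    colnames(vals) <- paste(fam, colnames(vals), sep = "_")
    blocks[[fam]] <- vals
    fam_tags <- c(fam_tags, setNames(rep(fam, ncol(vals)), colnames(vals)))
  }
  full <- do.call(cbind, blocks)
  ok <- ok & apply(full, 1, function(r) all(is.finite(r)))
  if (!any(ok)) stop("descriptor computation failed for all molecules")
  out <- full[ok, , drop = FALSE]
  rownames(out) <- ids[ok]
  fm <- feature_matrix(out, kind = "descriptor", family = fam_tags)
  attr(fm, "failures") <- ids[!ok]
  fm
}

#' Descriptor family manifest
#'
#' @return A data.frame listing each descriptor family, the number of
#'   columns this package computes for it, and the column names.
#' @export
descriptor_manifest <- function() {
  probe <- molecule_record("CC(=O)Oc1ccccc1C(=O)O", id = "probe")
  fm <- compute_descriptors(list(probe))
  fam <- attr(fm, "family")
  data.frame(family = DESCRIPTOR_FAMILIES,
             n_features = as.integer(table(fam)[DESCRIPTOR_FAMILIES]),
             features = vapply(DESCRIPTOR_FAMILIES, function(f)
               paste(names(fam)[fam == f], collapse = ","), character(1)),
             row.names = NULL)
}
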