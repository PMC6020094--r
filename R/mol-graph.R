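# Internal molecular graph: heavy atoms with element, formal charge and
# attached-hydrogen counts, plus a heavy-atom bond table with (kekulized)
# bond orders. Built from an Open Babel molblock parsed by ChemmineR; all
# graph-walking descriptor and fingerprint code operates on this structure.

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
                   Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26,
                   Cu = 29, Zn = 30, Br = 35, Rb = 37, Sr = 38, I = 53,
                   Cs = 55, Ba = 56, Li = 3, Be = 4)

ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Na = 22.99, Mg = 24.305, Si = 28.086, P = 30.974,
                 S = 32.06, Cl = 35.453, K = 39.098, Ca = 40.078, Fe = 55.845,
                 Cu = 63.546, Zn = 65.38, Br = 79.904, Rb = 85.468,
                 Sr = 87.62, I = 126.904, Cs = 132.905, Ba = 137.327,
                 Li = 6.941, Be = 9.012)

PAULING_EN <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                Na = 0.93, Mg = 1.31, Si = 1.90, P = 2.19, S = 2.58,
                Cl = 3.16, K = 0.82, Ca = 1.00, Fe = 1.83, Cu = 1.90,
                Zn = 1.65, Br = 2.96, Rb = 0.82, Sr = 0.95, I = 2.66,
                Cs = 0.79, Ba = 0.89, Li = 0.98, Be = 1.57)

# Alkali / alkaline-earth metals whose bonds to O/N/S are cleaved when
# washing "simple salts".
SALT_METALS <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba")

# molfile atom-line charge codes -> formal charge
.molfile_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  out
}

# Parse one SDF block (text, with explicit hydrogens) into a mol_graph.
# Hydrogens are collapsed onto their heavy neighbours as nH counts.
parse_molblock <- function(sdf_text) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdf_text, tmp)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  charges <- if ("C6" %in% colnames(ab)) .molfile_charge(ab[, "C6"]) else
    rep(0L, nrow(ab))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0, ncol = 7)
  bonds <- if (nrow(bb) > 0)
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  else data.frame(from = integer(), to = integer(), order = integer())

  heavy <- which(elements != "H")
  idx <- integer(length(elements))
  idx[heavy] <- seq_along(heavy)
  nH <- integer(length(heavy))
  keep <- logical(nrow(bonds))
  for (b in seq_len(nrow(bonds))) {
    f <- bonds$from[b]; t <- bonds$to[b]
    fh <- elements[f] == "H"; th <- elements[t] == "H"
    if (fh && th) next                   # molecular hydrogen fragment
    if (fh) nH[idx[t]] <- nH[idx[t]] + 1L
    else if (th) nH[idx[f]] <- nH[idx[f]] + 1L
    else keep[b] <- TRUE
  }
  hb <- bonds[keep, , drop = FALSE]
  hb$from <- idx[hb$from]; hb$to <- idx[hb$to]
  structure(list(
    elements = elements[heavy],
    charge = charges[heavy],
    nH = nH,
    bonds = hb,
    n_heavy = length(heavy)
  ), class = "mol_graph")
}

# igraph view of the heavy-atom skeleton (isolated atoms included).
graph_as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$bonds[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n_heavy))
  )
}

# Adjacency list: for each heavy atom, data.frame(nbr, order).
graph_adjacency <- function(g) {
  adj <- rep(list(data.frame(nbr = integer(), order = integer())), g$n_heavy)
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$from[k]]] <- rbind(adj[[b$from[k]]],
                              data.frame(nbr = b$to[k], order = b$order[k]))
    adj[[b$to[k]]] <- rbind(adj[[b$to[k]]],
                            data.frame(nbr = b$from[k], order = b$order[k]))
  }
  adj
}

# Heavy-atom topological distance matrix.
graph_distances <- function(g) {
  if (g$n_heavy == 0) return(matrix(numeric(), 0, 0))
  igraph::distances(graph_as_igraph(g))
}

# Ring membership: an atom is in a ring iff it is incident to a bond that
# lies on a cycle (a non-bridge edge).
graph_ring_atoms <- function(g) {
  out <- rep(FALSE, g$n_heavy)
  if (nrow(g$bonds) == 0) return(out)
  ig <- graph_as_igraph(g)
  br <- igraph::bridges(ig)
  ends <- igraph::ends(ig, igraph::E(ig))
  cyc <- setdiff(seq_len(nrow(ends)), as.integer(br))
  for (e in cyc) out[as.integer(ends[e, ])] <- TRUE
  out
}

graph_ring_bonds <- function(g) {
  if (nrow(g$bonds) == 0) return(logical(0))
  ig <- graph_as_igraph(g)
  br <- as.integer(igraph::bridges(ig))
  !(seq_len(nrow(g$bonds)) %in% br)
}

# Molecular weight including attached hydrogens.
graph_mw <- function(g, atoms = seq_len(g$n_heavy)) {
  if (length(atoms) == 0) return(0)
  m <- ATOMIC_MASS[g$elements[atoms]]
  m[is.na(m)] <- 0
  sum(m) + sum(g$nH[atoms]) * ATOMIC_MASS[["H"]]
}

# Write a V2000 molblock for a subset of heavy atoms (implicit hydrogens;
# formal charges carried as M CHG). Used to turn washed fragments back into
# canonical SMILES through Open Babel.
graph_to_molblock <- function(g, atoms = seq_len(g$n_heavy), title = "") {
  atoms <- sort(atoms)
  idx <- integer(g$n_heavy)
  idx[atoms] <- seq_along(atoms)
  b <- g$bonds[g$bonds$from %in% atoms & g$bonds$to %in% atoms, , drop = FALSE]
  lines <- c(title, " admetkit", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                            length(atoms), nrow(b)))
  for (a in atoms) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$elements[a]))
  }
  for (k in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              idx[b$from[k]], idx[b$to[k]], b$order[k]))
  }
  chg <- which(g$charge[atoms] != 0)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, g$charge[atoms][grp]), collapse = "")))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  paste0(paste(lines, collapse = "\n"), "\n")
}
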