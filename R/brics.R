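# BRICS fragmentation (Degen et al., ChemMedChem 2008) implemented directly
# on the annotated molecular graph. Each of the sixteen link environments is
# an atom predicate; a single acyclic bond is a cleavage site when its two
# endpoints match one of the allowed environment pairs (the L7/L7 pair
# cleaves acyclic double bonds). No installed R package provides BRICS, so
# the published rule set is encoded here.

# Adjacency with bond annotations: for each atom, the rows of mol$bonds
# that touch it plus the neighbor index.
mol_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b$i[r]]] <- rbind(nb[[b$i[r]]], c(j = b$j[r], row = r))
    nb[[b$j[r]]] <- rbind(nb[[b$j[r]]], c(j = b$i[r], row = r))
  }
  nb
}

# returns matrix of (neighbor index, bond row) or NULL
.nbrs <- function(env, i) env$nb[[i]]

brics_env_match <- function(mol, nb, i, env) {
  a <- mol$atoms
  b <- mol$bonds
  sym <- a$symbol[i]; arom <- a$aromatic[i]; deg <- a$degree[i]
  rows <- nb[[i]]
  nj <- if (is.null(rows)) integer(0) else rows[, "j"]
  nr <- if (is.null(rows)) integer(0) else rows[, "row"]
  ord <- b$order[nr]
  ring <- b$in_ring[nr]
  nsym <- a$symbol[nj]
  narom <- a$aromatic[nj]
  has_dbl_O <- any(ord == 2 & nsym == "O")
  switch(env,
    L1 = sym == "C" && !arom && deg == 3 && has_dbl_O &&
      any(ord != 2 & nsym %in% c("C", "N", "O")),
    L3 = sym == "O" && !arom && deg == 2 &&
      any(ord == 1 & !ring & nsym == "C"),
    L4 = sym == "C" && !arom && deg >= 2 && !any(ord == 2) &&
      any(ord == 1 & !ring & nsym == "C"),
    L5 = sym == "N" && !arom && deg >= 2 && !any(ord == 2) &&
      all(nsym %in% c("C", "S")) &&
      !(a$in_ring[i] && any(ring & nsym == "C" & !narom &
                              vapply(nj, function(cc) {
                                crows <- nb[[cc]]
                                any(b$order[crows[, "row"]] == 2 &
                                      a$symbol[crows[, "j"]] == "O")
                              }, logical(1)))),
    L6 = sym == "C" && !arom && deg == 3 && !a$in_ring[i] && has_dbl_O &&
      any(ord == 1 & !ring & nsym %in% c("C", "N", "O")),
    L7 = sym == "C" && !arom && deg %in% c(2, 3) && any(nsym == "C"),
    L8 = sym == "C" && !arom && !a$in_ring[i] && deg >= 2 &&
      all(ord == 1),
    L9 = sym == "N" && arom && a$charge[i] == 0 &&
      sum(narom & ring) >= 2,
    L10 = sym == "N" && !arom && a$in_ring[i] &&
      any(ring & nsym == "C" & !narom &
            vapply(nj, function(cc) {
              crows <- nb[[cc]]
              any(b$order[crows[, "row"]] == 2 &
                    a$symbol[crows[, "j"]] == "O")
            }, logical(1))),
    L11 = sym == "S" && !arom && deg == 2 &&
      any(ord == 1 & !ring & nsym == "C"),
    L12 = sym == "S" && deg == 4 && sum(ord == 2 & nsym == "O") == 2 &&
      any(nsym == "C"),
    L13 = sym == "C" && !arom && a$in_ring[i] &&
      sum(ord == 1 & ring & !narom & nsym %in% c("C", "N", "O", "S")) >= 2 &&
      any(ord == 1 & ring & !narom & nsym %in% c("N", "O", "S")),
    L14 = sym == "C" && arom && sum(narom & ring) >= 2 &&
      any(narom & ring & nsym %in% c("N", "O", "S")),
    L15 = sym == "C" && !arom && a$in_ring[i] &&
      sum(ord == 1 & ring & !narom & nsym == "C") >= 2,
    L16 = sym == "C" && arom && sum(narom & ring & nsym == "C") >= 2,
    hmg_error("hmg_argument_error", sprintf("unknown BRICS environment %s", env))
  )
}

# allowed environment pairs; bond = required order of the cleaved bond
BRICS_PAIRS <- local({
  p <- rbind(
    c(1, 3), c(1, 5), c(1, 10),
    c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
    c(4, 5), c(4, 11),
    c(5, 12), c(5, 13), c(5, 14), c(5, 15), c(5, 16),
    c(6, 13), c(6, 14), c(6, 15), c(6, 16),
    c(7, 7),
    c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
    c(9, 13), c(9, 14), c(9, 15), c(9, 16),
    c(10, 13), c(10, 14), c(10, 15), c(10, 16),
    c(11, 13), c(11, 14), c(11, 15), c(11, 16),
    c(13, 14), c(13, 15), c(13, 16),
    c(14, 14), c(14, 15), c(14, 16),
    c(15, 16),
    c(16, 16)
  )
  data.frame(a = p[, 1], b = p[, 2],
             bond_order = ifelse(p[, 1] == 7, 2L, 1L))
})

# Find the BRICS cleavage bonds of a parsed molecule. Returns a data frame
# with one row per cleaved bond: atom indices i, j and the matched link
# environment numbers env_i, env_j.
find_brics_bonds <- function(mol) {
  nb <- mol_neighbors(mol)
  b <- mol$bonds
  out <- data.frame(i = integer(0), j = integer(0),
                    env_i = integer(0), env_j = integer(0))
  if (nrow(b) == 0) return(out)
  env_cache <- matrix(NA, nrow = nrow(mol$atoms), ncol = 16)
  matches <- function(i, e) {
    if (is.na(env_cache[i, e])) {
      env_cache[i, e] <<- brics_env_match(mol, nb, i, paste0("L", e))
    }
    env_cache[i, e]
  }
  for (r in seq_len(nrow(b))) {
    if (b$in_ring[r]) next
    hit <- NULL
    for (p in seq_len(nrow(BRICS_PAIRS))) {
      ea <- BRICS_PAIRS$a[p]; eb <- BRICS_PAIRS$b[p]
      if (b$order[r] != BRICS_PAIRS$bond_order[p]) next
      if (matches(b$i[r], ea) && matches(b$j[r], eb)) {
        hit <- c(b$i[r], b$j[r], ea, eb); break
      }
      if (matches(b$j[r], ea) && matches(b$i[r], eb)) {
        hit <- c(b$j[r], b$i[r], ea, eb); break
      }
    }
    if (!is.null(hit)) {
      out <- rbind(out, data.frame(i = hit[1], j = hit[2],
                                   env_i = hit[3], env_j = hit[4]))
    }
  }
  out
}

#' BRICS fragmentation of a molecule
#'
#' Cleaves the molecule at BRICS bonds (single acyclic bonds between allowed
#' link environments) and labels each atom with its fragment.
#'
#' @param smiles a SMILES string.
#' @return an object of class `fragment_map`: list with `fragment_id`
#'   (integer per atom, numbered by first occurrence), `n_fragments`, and
#'   `breakpoints` (data frame `i`, `j`, `env_i`, `env_j`).
#' @export
brics_fragments <- function(smiles) {
  mol <- if (inherits(smiles, "hmg_mol")) smiles else parse_smiles(smiles)
  bp <- find_brics_bonds(mol)
  n <- nrow(mol$atoms)
  keep <- mol$bonds
  if (nrow(bp) > 0) {
    cut_key <- paste(pmin(bp$i, bp$j), pmax(bp$i, bp$j))
    bond_key <- paste(pmin(keep$i, keep$j), pmax(keep$i, keep$j))
    keep <- keep[!(bond_key %in% cut_key), , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(keep) > 0) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(keep[, c("i", "j")]))))
  }
  memb <- igraph::components(g)$membership
  # renumber fragments by first atom occurrence for determinism
  first <- match(unique(memb), memb)
  relabel <- order(order(first))
  fragment_id <- relabel[match(memb, unique(memb))]
  structure(list(
    fragment_id = as.integer(fragment_id),
    n_fragments = length(unique(fragment_id)),
    breakpoints = bp
  ), class = "fragment_map")
}
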