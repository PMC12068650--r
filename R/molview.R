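# Molecule view: atom and BRICS-fragment nodes; bond, reaction and join
# edges; raw featurization and Laplacian positional encodings.
#
# Feature schema (per type; dimensions may differ across types because the
# encoder maps each type through its own input projection):
#   atom      element one-hot (10) + degree 0-5 one-hot (6) + formal charge
#             -2..+2 one-hot (5) + aromatic bit + hybridization one-hot (4)
#             + ring bit                                     -> 27
#   fragment  mean of member-atom features + heavy-atom count -> 28
#   bond      order one-hot (single/double/triple/aromatic) + conjugation
#             bit + ring bit                                  -> 6
#   reaction  BRICS link-environment two-hot over L1..L16     -> 16
#   join      constant 1                                      -> 1

POS_ENC_DIM <- 8L

#' Per-type raw feature dimensions of the HMG schema
#' @param d_kg drug-KG embedding dimension (feature width of the DNode).
#' @return list with `node` and `edge` named dimension vectors and `k_pos`.
#' @export
hmg_feature_dims <- function(d_kg = 8L) {
  list(
    node = c(atom = 27L, fragment = 28L,
             element = nrow(PERIODIC_TABLE) + EKG_ATTR_DIM,
             functional_group = EKG_ATTR_DIM, dnode = as.integer(d_kg)),
    edge = c(bond = 6L, reaction = 16L, join = 1L, AE = 4L, FrFu = 4L,
             EE = EKG_ATTR_DIM, FuFu = EKG_ATTR_DIM,
             EFu = EKG_ATTR_DIM + length(ELEMENT_KG_RELATIONS),
             AD = 4L, FrD = 4L),
    k_pos = POS_ENC_DIM
  )
}

one_hot <- function(value, levels) {
  as.numeric(levels == value)
}

atom_feature <- function(mol, i) {
  a <- mol$atoms[i, ]
  c(one_hot(a$symbol, PERIODIC_TABLE$symbol),
    one_hot(min(a$degree, 5L), 0:5),
    one_hot(max(-2L, min(2L, a$charge)), -2:2),
    as.numeric(a$aromatic),
    one_hot(a$hybrid, c("sp", "sp2", "sp3", "other")),
    as.numeric(a$in_ring))
}

bond_feature <- function(mol, r) {
  b <- mol$bonds[r, ]
  cat <- if (b$aromatic) "aromatic" else
    c("single", "double", "triple")[b$order]
  c(one_hot(cat, c("single", "double", "triple", "aromatic")),
    as.numeric(b$conjugated), as.numeric(b$in_ring))
}

reaction_feature <- function(env_i, env_j) {
  f <- numeric(16)
  f[env_i] <- 1; f[env_j] <- 1
  f
}

# one-hot over the four hub relation types used for AE/FrFu/AD/FrD edges
hub_relation_feature <- function(type) {
  one_hot(type, c("AE", "FrFu", "AD", "FrD"))
}

# Laplacian eigenvector positional encodings of the atom-bond subgraph:
# eigenvectors of L = D - A for the smallest non-trivial eigenvalues,
# sign-fixed so each vector's first nonzero entry is positive, zero-padded
# to k columns. Fragment and KG-derived nodes receive zeros.
laplacian_pe <- function(mol, k = POS_ENC_DIM) {
  n <- nrow(mol$atoms)
  out <- matrix(0, n, k)
  if (n < 2 || nrow(mol$bonds) == 0) return(out)
  A <- matrix(0, n, n)
  A[cbind(mol$bonds$i, mol$bonds$j)] <- 1
  A[cbind(mol$bonds$j, mol$bonds$i)] <- 1
  L <- diag(rowSums(A)) - A
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values)           # ascending
  take <- ord[-1]                    # drop the trivial constant vector
  take <- take[seq_len(min(k, length(take)))]
  for (c in seq_along(take)) {
    v <- eig$vectors[, take[c]]
    nz <- which(abs(v) > 1e-8)
    if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
    out[, c] <- v
  }
  out
}

#' Build the molecule view of a SMILES string
#'
#' Nodes are heavy atoms and BRICS fragments; edges are chemical bonds,
#' reaction edges between fragments joined at a BRICS breakpoint, and join
#' edges linking each atom to its fragment. Every relation is materialized
#' in both directions. The returned graph is unfeaturized; run
#' [featurize()] to fill raw features.
#'
#' @param smiles a SMILES string.
#' @return an `hmgraph` with view tag `"M"`.
#' @export
build_molecule_view <- function(smiles) {
  mol <- parse_smiles(smiles)
  fmap <- brics_fragments(mol)
  n <- nrow(mol$atoms)

  atom_ids <- pad_id("a", seq_len(n))
  frag_ids <- pad_id("f", seq_len(fmap$n_fragments))
  nodes <- data.frame(
    id = c(atom_ids, frag_ids),
    type = c(rep("atom", n), rep("fragment", fmap$n_fragments)),
    ref = c(as.character(seq_len(n)), as.character(seq_len(fmap$n_fragments))),
    stringsAsFactors = FALSE
  )

  base <- list()
  b <- mol$bonds
  if (nrow(b) > 0) {
    base[[length(base) + 1]] <- data.frame(
      src = atom_ids[b$i], dst = atom_ids[b$j], type = "bond",
      intermediate = NA_character_, relation = NA_character_,
      ref = as.character(seq_len(nrow(b))))
  }
  bp <- fmap$breakpoints
  if (nrow(bp) > 0) {
    base[[length(base) + 1]] <- data.frame(
      src = frag_ids[fmap$fragment_id[bp$i]],
      dst = frag_ids[fmap$fragment_id[bp$j]], type = "reaction",
      intermediate = NA_character_, relation = NA_character_,
      ref = paste0(bp$env_i, "-", bp$env_j))
  }
  base[[length(base) + 1]] <- data.frame(
    src = atom_ids, dst = frag_ids[fmap$fragment_id], type = "join",
    intermediate = NA_character_, relation = NA_character_,
    ref = NA_character_)

  base <- do.call(rbind, base)
  rev <- base; rev$src <- base$dst; rev$dst <- base$src
  edges <- rbind(base, rev)

  g <- structure(list(view = "M", smiles = smiles, nodes = nodes,
                      edges = edges, node_features = NULL,
                      edge_features = NULL, pos = NULL),
                 class = "hmgraph")
  g <- sort_hmgraph(g)
  g$edges <- cbind(id = pad_id("e", seq_len(nrow(g$edges))), g$edges,
                   stringsAsFactors = FALSE)
  validate_hmgraph(g)
  g
}

#' Fill the raw features of a molecule-view graph
#'
#' Computes atom, fragment, bond, reaction and join features per the schema
#' in [hmg_feature_dims()], plus Laplacian positional encodings for atom
#' nodes (zeros for all other node types). Knowledge-derived nodes and
#' edges added by the view-augmentation step keep the features they were
#' built with; unknown types raise a schema error.
#'
#' @param g an `hmgraph`.
#' @return the graph with `node_features`, `edge_features` and `pos` filled.
#' @export
featurize <- function(g) {
  mol <- parse_smiles(g$smiles)
  fmap <- brics_fragments(mol)
  dims <- hmg_feature_dims()
  pe <- laplacian_pe(mol)

  afeat <- lapply(seq_len(nrow(mol$atoms)), function(i) atom_feature(mol, i))
  frag_feat <- lapply(seq_len(fmap$n_fragments), function(f) {
    members <- which(fmap$fragment_id == f)
    m <- do.call(rbind, afeat[members])
    c(colMeans(m), length(members))
  })

  node_features <- vector("list", nrow(g$nodes))
  pos <- matrix(0, nrow(g$nodes), POS_ENC_DIM)
  for (i in seq_len(nrow(g$nodes))) {
    ty <- g$nodes$type[i]
    node_features[[i]] <- switch(ty,
      atom = {
        ai <- as.integer(g$nodes$ref[i])
        pos[i, ] <- pe[ai, ]
        afeat[[ai]]
      },
      fragment = frag_feat[[as.integer(g$nodes$ref[i])]],
      element = , functional_group = , dnode = {
        f <- if (!is.null(g$node_features)) g$node_features[[i]] else NULL
        if (is.null(f)) hmg_error("hmg_schema_error",
          sprintf("node type '%s' has no precomputed feature", ty))
        f
      },
      hmg_error("hmg_schema_error", sprintf("unknown node type '%s'", ty))
    )
  }

  edge_features <- vector("list", nrow(g$edges))
  for (i in seq_len(nrow(g$edges))) {
    ty <- g$edges$type[i]
    edge_features[[i]] <- switch(ty,
      bond = bond_feature(mol, as.integer(g$edges$ref[i])),
      reaction = {
        envs <- as.integer(strsplit(g$edges$ref[i], "-", fixed = TRUE)[[1]])
        reaction_feature(envs[1], envs[2])
      },
      join = 1,
      AE = , FrFu = , AD = , FrD = , EE = , FuFu = , EFu = {
        f <- if (!is.null(g$edge_features)) g$edge_features[[i]] else NULL
        if (is.null(f)) hmg_error("hmg_schema_error",
          sprintf("edge type '%s' has no precomputed feature", ty))
        f
      },
      hmg_error("hmg_schema_error", sprintf("unknown edge type '%s'", ty))
    )
  }

  for (i in seq_len(nrow(g$nodes))) {
    want <- dims$node[[g$nodes$type[i]]]
    if (!is.na(want) && g$nodes$type[i] != "dnode" &&
        length(node_features[[i]]) != want) {
      hmg_error("hmg_schema_error",
                sprintf("node %s (%s): feature length %d, expected %d",
                        g$nodes$id[i], g$nodes$type[i],
                        length(node_features[[i]]), want))
    }
  }

  g$node_features <- node_features
  g$edge_features <- edge_features
  if (is.null(g$pos) || g$view == "M") {
    g$pos <- pos
  } else {
    # keep existing rows for KG nodes (they are zero anyway), refresh atoms
    atom_rows <- which(g$nodes$type == "atom")
    g$pos[atom_rows, ] <- pos[atom_rows, ]
  }
  g
}
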