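# Shared fixtures, built once per test session.

fx <- new.env()

fx_ekg <- function() {
  if (is.null(fx$ekg)) fx$ekg <- gen_element_kg(seed = 7)
  fx$ekg
}

fx_dkg <- function() {
  if (is.null(fx$dkg)) fx$dkg <- gen_drug_kg(n_drugs = 12,
                                             n_other_entities = 10,
                                             d_kg = 8, seed = 3)
  fx$dkg
}

fx_pool <- function() {
  if (is.null(fx$pool)) fx$pool <- gen_molecule_pool(24, 0.3, fx_dkg(),
                                                     seed = 11)
  fx$pool
}

fx_mol_graph <- function(smiles) {
  key <- paste0("m_", smiles)
  if (is.null(fx[[key]])) fx[[key]] <- featurize(build_molecule_view(smiles))
  fx[[key]]
}

# A small random heterogeneous graph with valid reverse-paired edges,
# random features of the schema widths, for encoder oracle tests.
rand_graph <- function(seed, n_max = 8L) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  n_atom <- max(2L, ceiling(n / 2))
  types <- c(rep("atom", n_atom), rep("fragment", n - n_atom))
  ids <- sprintf("n%02d", seq_len(n))
  dims <- hmg_feature_dims()
  pairs <- t(combn(n, 2))
  ne <- sample(2:min(10L, nrow(pairs)), 1)
  sel <- pairs[sample(nrow(pairs), ne), , drop = FALSE]
  etype <- sample(c("bond", "join"), ne, replace = TRUE)
  base <- data.frame(src = ids[sel[, 1]], dst = ids[sel[, 2]],
                     type = etype, intermediate = NA_character_,
                     relation = NA_character_, stringsAsFactors = FALSE)
  rev <- base; rev$src <- base$dst; rev$dst <- base$src
  edges <- rbind(base, rev)
  edges <- cbind(id = sprintf("e%03d", seq_len(nrow(edges))), edges,
                 stringsAsFactors = FALSE)
  nf <- lapply(types, function(t) stats::runif(dims$node[[t]], -1, 1))
  ef <- lapply(edges$type, function(t) stats::runif(dims$edge[[t]], -1, 1))
  g <- structure(list(
    view = "M", smiles = "<synthetic>",
    nodes = data.frame(id = ids, type = types, ref = ids,
                       stringsAsFactors = FALSE),
    edges = edges, node_features = nf, edge_features = ef,
    pos = matrix(stats::runif(n * dims$k_pos, -1, 1), n)
  ), class = "hmgraph")
  validate_hmgraph(g)
  g
}

# reorder the nodes (and shuffle edge rows) of a graph, carrying each
# node's features and positional vector with it
permute_graph <- function(g, seed) {
  set.seed(seed)
  perm <- sample(nrow(g$nodes))
  g$nodes <- g$nodes[perm, , drop = FALSE]
  g$node_features <- g$node_features[perm]
  g$pos <- g$pos[perm, , drop = FALSE]
  rownames(g$nodes) <- NULL
  eperm <- sample(nrow(g$edges))
  g$edges <- g$edges[eperm, , drop = FALSE]
  g$edge_features <- g$edge_features[eperm]
  rownames(g$edges) <- NULL
  g
}
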