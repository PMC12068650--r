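# The heterogeneous molecular graph (HMG): a typed, directed, multi-edge
# graph shared by the molecule (M), element (EM) and drug (DM) views.
# Every chemistry-derived undirected relation is stored as two directed
# edges; parallel edges are permitted only for the knowledge-derived
# EE / FuFu / EFu types of the element view.

HMG_NODE_TYPES <- c("atom", "fragment", "element", "functional_group", "dnode")
HMG_EDGE_TYPES <- c("bond", "reaction", "join", "AE", "FrFu", "EE", "FuFu",
                    "EFu", "AD", "FrD")
HMG_SCHEMA_VERSION <- "hmgraph/1"

# canonical sort ranks used for order-stable construction
.node_rank <- stats::setNames(seq_along(HMG_NODE_TYPES), HMG_NODE_TYPES)
.edge_rank <- stats::setNames(seq_along(HMG_EDGE_TYPES), HMG_EDGE_TYPES)

new_hmgraph <- function(view, smiles, nodes, edges, node_features = NULL,
                        edge_features = NULL, pos = NULL) {
  g <- structure(list(
    view = view, smiles = smiles,
    nodes = nodes, edges = edges,
    node_features = node_features, edge_features = edge_features,
    pos = pos
  ), class = "hmgraph")
  validate_hmgraph(g)
  g
}

#' Validate an HMGraph's structural invariants
#'
#' Checks type vocabularies, that edges reference existing nodes, that each
#' directed edge has its reverse (same type, same intermediate), that
#' parallel edges occur only for EE/FuFu/EFu in the element view, and that a
#' drug view holds exactly one DNode.
#' @param g an `hmgraph`.
#' @return the graph, invisibly; errors on violation.
#' @export
validate_hmgraph <- function(g) {
  assert_that(g$view %in% c("M", "EM", "DM"), "hmg_schema_error",
              "view tag must be M, EM or DM")
  nd <- g$nodes; ed <- g$edges
  assert_that(all(nd$type %in% HMG_NODE_TYPES), "hmg_schema_error",
              sprintf("unknown node type(s): %s",
                      paste(setdiff(nd$type, HMG_NODE_TYPES), collapse = ",")))
  assert_that(all(ed$type %in% HMG_EDGE_TYPES), "hmg_schema_error",
              sprintf("unknown edge type(s): %s",
                      paste(setdiff(ed$type, HMG_EDGE_TYPES), collapse = ",")))
  assert_that(!anyDuplicated(nd$id), "hmg_integrity_error",
              "duplicate node ids")
  assert_that(all(c(ed$src, ed$dst) %in% nd$id), "hmg_integrity_error",
              "edge references unknown node")
  if (nrow(ed) > 0) {
    key <- paste(ed$type, ed$src, ed$dst, ed$intermediate, sep = "\r")
    rkey <- paste(ed$type, ed$dst, ed$src, ed$intermediate, sep = "\r")
    fwd <- table(key); rev <- table(rkey)
    assert_that(identical(sort(names(fwd)), sort(names(rev))) &&
                  all(fwd[sort(names(fwd))] == rev[sort(names(fwd))]),
                "hmg_integrity_error",
                "directed edges must come in reverse pairs")
    multi <- ed[duplicated(paste(ed$src, ed$dst, sep = "\r")) |
                  duplicated(paste(ed$src, ed$dst, sep = "\r"),
                             fromLast = TRUE), , drop = FALSE]
    bad <- multi$type[!multi$type %in% c("EE", "FuFu", "EFu")]
    assert_that(length(bad) == 0, "hmg_integrity_error",
                sprintf("parallel edges only allowed for EE/FuFu/EFu (got %s)",
                        paste(unique(bad), collapse = ",")))
  }
  if (g$view == "DM") {
    assert_that(sum(nd$type == "dnode") == 1L, "hmg_integrity_error",
                "a drug view must hold exactly one dnode")
  }
  invisible(g)
}

#' @export
print.hmgraph <- function(x, ...) {
  cat(sprintf("<hmgraph view=%s smiles=%s>\n", x$view, x$smiles))
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%s)", paste(sprintf("%s=%d", names(table(x$nodes$type)),
                                    table(x$nodes$type)), collapse = " ")), "\n")
  cat("  directed edges:", nrow(x$edges),
      sprintf("(%s)", paste(sprintf("%s=%d", names(table(x$edges$type)),
                                    table(x$edges$type)), collapse = " ")), "\n")
  invisible(x)
}

#' Node and edge type counts of a graph
#' @param g an `hmgraph`.
#' @return list with `node_types` and `edge_types` tables.
#' @export
hmg_type_counts <- function(g) {
  list(node_types = table(g$nodes$type), edge_types = table(g$edges$type))
}

has_features <- function(g) {
  !is.null(g$node_features) && !is.null(g$edge_features) &&
    length(g$node_features) == nrow(g$nodes) &&
    (nrow(g$edges) == 0 || length(g$edge_features) == nrow(g$edges))
}

# canonical ordering applied after every construction step so repeated
# builds are byte-identical
sort_hmgraph <- function(g) {
  no <- order(.node_rank[g$nodes$type], g$nodes$id)
  g$nodes <- g$nodes[no, , drop = FALSE]
  rownames(g$nodes) <- NULL
  if (!is.null(g$node_features)) g$node_features <- g$node_features[no]
  if (!is.null(g$pos)) g$pos <- g$pos[no, , drop = FALSE]
  if (nrow(g$edges) > 0) {
    eo <- order(.edge_rank[g$edges$type], g$edges$src, g$edges$dst,
                g$edges$intermediate)
    g$edges <- g$edges[eo, , drop = FALSE]
    rownames(g$edges) <- NULL
    if (!is.null(g$edge_features)) g$edge_features <- g$edge_features[eo]
  }
  g
}

#' Serialize an HMGraph to its JSON schema
#'
#' Lossless, diffable representation: a version header, the view tag, the
#' source SMILES, and node/edge records with type labels, feature vectors
#' and positional encodings.
#' @param g an `hmgraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
serialize_graph <- function(g, path) {
  validate_hmgraph(g)
  obj <- list(
    schema = HMG_SCHEMA_VERSION,
    view = g$view,
    smiles = g$smiles,
    nodes = lapply(seq_len(nrow(g$nodes)), function(i) {
      list(id = g$nodes$id[i], type = g$nodes$type[i], ref = g$nodes$ref[i],
           feature = if (!is.null(g$node_features)) g$node_features[[i]],
           pos = if (!is.null(g$pos)) as.numeric(g$pos[i, ]))
    }),
    edges = lapply(seq_len(nrow(g$edges)), function(i) {
      list(id = g$edges$id[i], src = g$edges$src[i], dst = g$edges$dst[i],
           type = g$edges$type[i],
           intermediate = g$edges$intermediate[i],
           relation = g$edges$relation[i],
           feature = if (!is.null(g$edge_features)) g$edge_features[[i]])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read an HMGraph back from its JSON schema
#' @param path file written by [serialize_graph()].
#' @return an `hmgraph`; errors on version mismatch or tampered labels.
#' @export
deserialize_graph <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, HMG_SCHEMA_VERSION)) {
    hmg_error("hmg_version_error",
              sprintf("schema version mismatch: got '%s', expected '%s'",
                      obj$schema %||% "<none>", HMG_SCHEMA_VERSION))
  }
  grab <- function(rec, field) rec[[field]] %||% NA_character_
  nodes <- data.frame(
    id = vapply(obj$nodes, grab, "", "id"),
    type = vapply(obj$nodes, grab, "", "type"),
    ref = vapply(obj$nodes, grab, "", "ref"),
    stringsAsFactors = FALSE
  )
  node_features <- lapply(obj$nodes, function(r) as.numeric(unlist(r$feature)))
  pos <- do.call(rbind, lapply(obj$nodes, function(r)
    as.numeric(unlist(r$pos))))
  edges <- data.frame(
    id = vapply(obj$edges, grab, "", "id"),
    src = vapply(obj$edges, grab, "", "src"),
    dst = vapply(obj$edges, grab, "", "dst"),
    type = vapply(obj$edges, grab, "", "type"),
    intermediate = vapply(obj$edges, grab, "", "intermediate"),
    relation = vapply(obj$edges, grab, "", "relation"),
    stringsAsFactors = FALSE
  )
  edge_features <- lapply(obj$edges, function(r) as.numeric(unlist(r$feature)))
  if (nrow(edges) == 0) {
    edges <- data.frame(id = character(0), src = character(0),
                        dst = character(0), type = character(0),
                        intermediate = character(0), relation = character(0))
    edge_features <- list()
  }
  new_hmgraph(obj$view, obj$smiles, nodes, edges,
              node_features = node_features, edge_features = edge_features,
              pos = pos)
}
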