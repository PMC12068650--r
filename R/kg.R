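# Typed knowledge-graph containers: an elemental KG (class / chemical /
# property levels) and a drug KG with per-entity embeddings. Both are plain
# S3 lists over data frames so they serialize losslessly to TSV.

new_element_kg <- function(entities, relations, triples, attributes) {
  kg <- structure(list(entities = entities, relations = relations,
                       triples = triples, attributes = attributes),
                  class = "element_kg")
  validate_element_kg(kg)
  kg
}

validate_element_kg <- function(kg) {
  ent <- kg$entities
  assert_that(all(c("id", "level", "kind") %in% names(ent)),
              "hmg_schema_error", "element KG entities need id/level/kind")
  assert_that(!anyDuplicated(ent$id), "hmg_integrity_error",
              "duplicate entity ids in element KG")
  assert_that(all(ent$level %in% c("class", "chemical", "property")),
              "hmg_schema_error", "unknown entity level in element KG")
  assert_that(all(ent$kind %in% c("class", "element", "functional_group",
                                  "property")),
              "hmg_schema_error", "unknown entity kind in element KG")
  tr <- kg$triples
  missing <- setdiff(c(tr$head, tr$tail), ent$id)
  if (length(missing) > 0) {
    hmg_error("hmg_integrity_error",
              sprintf("triples reference unknown entities: %s",
                      paste(missing, collapse = ",")))
  }
  assert_that(all(tr$relation %in% kg$relations), "hmg_integrity_error",
              "triple relation outside declared vocabulary")
  assert_that(all(tr$head != tr$tail), "hmg_integrity_error",
              "self-loop triple in element KG")
  fg <- ent[ent$kind == "functional_group", , drop = FALSE]
  if (nrow(fg) > 0) {
    ok <- vapply(fg$smarts, smarts_is_valid, logical(1))
    assert_that(all(ok), "hmg_schema_error",
                sprintf("invalid SMARTS for functional group(s): %s",
                        paste(fg$id[!ok], collapse = ",")))
  }
  el <- ent[ent$kind == "element", , drop = FALSE]
  assert_that(all(nchar(el$symbol) %in% 1:2), "hmg_schema_error",
              "element symbols must be one or two letters")
  assert_that(all(ent$id %in% rownames(kg$attributes)), "hmg_schema_error",
              "every element-KG entity needs an attribute vector")
  invisible(kg)
}

new_drug_kg <- function(entities, relations, triples, embeddings) {
  kg <- structure(list(entities = entities, relations = relations,
                       triples = triples, embeddings = embeddings),
                  class = "drug_kg")
  validate_drug_kg(kg)
  kg
}

DRUG_KG_CATEGORIES <- c("drug", "gene", "compound", "disease", "process",
                        "side-effect", "symptom")

validate_drug_kg <- function(kg) {
  ent <- kg$entities
  assert_that(all(c("id", "category") %in% names(ent)), "hmg_schema_error",
              "drug KG entities need id/category")
  assert_that(!anyDuplicated(ent$id), "hmg_integrity_error",
              "duplicate entity ids in drug KG")
  assert_that(all(ent$category %in% DRUG_KG_CATEGORIES), "hmg_schema_error",
              "unknown entity category in drug KG")
  tr <- kg$triples
  missing <- setdiff(c(tr$head, tr$tail), ent$id)
  if (length(missing) > 0) {
    hmg_error("hmg_integrity_error",
              sprintf("triples reference unknown entities: %s",
                      paste(missing, collapse = ",")))
  }
  assert_that(all(tr$relation %in% kg$relations), "hmg_integrity_error",
              "triple relation outside declared vocabulary")
  drugs <- ent$id[ent$category == "drug"]
  assert_that(all(drugs %in% rownames(kg$embeddings)), "hmg_schema_error",
              "every drug entity needs an embedding")
  invisible(kg)
}

#' Drug entity ids of a drug KG
#' @param dkg a `drug_kg`.
#' @return character vector of entity ids with category `"drug"`.
#' @export
drug_entities <- function(dkg) {
  dkg$entities$id[dkg$entities$category == "drug"]
}

#' Look up the embedding of a drug-KG entity
#' @param dkg a `drug_kg`.
#' @param id entity id.
#' @return numeric vector of dimension `d_kg`.
#' @export
drug_embedding <- function(dkg, id) {
  if (length(id) != 1L || !id %in% rownames(dkg$embeddings)) {
    hmg_error("hmg_lookup_error",
              sprintf("no embedding for drug-KG entity '%s'", id))
  }
  as.numeric(dkg$embeddings[id, ])
}

#' Replace the embedding table of a drug KG
#'
#' Hook for supplying externally trained knowledge-graph embeddings in place
#' of the generated stand-in vectors.
#' @param dkg a `drug_kg`.
#' @param embeddings numeric matrix with entity ids as rownames; must cover
#'   every drug entity and have constant width.
#' @return the updated `drug_kg`.
#' @export
set_drug_embeddings <- function(dkg, embeddings) {
  assert_that(is.matrix(embeddings) && !is.null(rownames(embeddings)),
              "hmg_schema_error", "embeddings must be a matrix with rownames")
  dkg$embeddings <- embeddings
  validate_drug_kg(dkg)
  dkg
}

# chemical-level entity ids (elements + functional groups)
chemical_entities <- function(ekg) {
  ekg$entities$id[ekg$entities$level == "chemical"]
}

# undirected adjacency over triples: for an entity, all (neighbor, relation)
# pairs regardless of triple direction
kg_neighbors <- function(kg, id) {
  tr <- kg$triples
  h <- tr[tr$head == id, c("tail", "relation")]
  t <- tr[tr$tail == id, c("head", "relation")]
  names(h) <- names(t) <- c("nbr", "relation")
  rbind(h, t)
}
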