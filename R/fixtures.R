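# Synthetic fixture generators: a curated mini elemental KG, a random drug
# KG with embeddings, and seeded molecule pools. These emulate the study
# conditions of knowledge-augmented molecular pre-training at desk scale:
# a three-level elemental KG (class / element-and-functional-group /
# property), a biological drug KG whose entities carry embedding vectors,
# and molecule pools in which only a minority fraction carries drug ids.

# Curated functional groups with literature SMARTS. The elements column
# lists which chemical elements participate (drives isPartOf triples).
FUNCTIONAL_GROUPS <- data.frame(
  name = c("Acetal", "Hydroxyl", "CarboxylicAcid", "Ester", "Amide",
           "PrimaryAmine", "Nitrile", "Ether", "Ketone", "Sulfonamide",
           "Haloalkane"),
  smarts = c("O[CH1][OX2H0]", "[OX2H]", "[CX3](=O)[OX2H1]",
             "[CX3](=O)[OX2H0][#6]", "[NX3][CX3](=[OX1])", "[NX3;H2][#6]",
             "[NX1]#[CX2]", "[OD2]([#6])[#6]", "[#6][CX3](=[OX1])[#6]",
             "[SX4](=[OX1])(=[OX1])[NX3]", "[#6][F,Cl,Br,I]"),
  elements = c("C,O,H", "O,H", "C,O,H", "C,O", "C,N,O", "C,N,H", "C,N",
               "C,O", "C,O", "S,N,O", "C,F,Cl,Br,I"),
  stringsAsFactors = FALSE
)

ELEMENT_CLASSES <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "S", "Cl", "P", "Br", "I"),
  class = c("ReactiveNonmetal", "ReactiveNonmetal", "ReactiveNonmetal",
            "ReactiveNonmetal", "Halogens", "ReactiveNonmetal", "Halogens",
            "ReactiveNonmetal", "Halogens", "Halogens"),
  stringsAsFactors = FALSE
)

ELEMENT_KG_RELATIONS <- c("isSubClassOf", "isPartOf", "hasWeight", "isInPeriod")

# attribute-vector width for element-KG entities
EKG_ATTR_DIM <- 8L

weight_bin <- function(w) {
  findInterval(w, c(0, 10, 20, 40, 90)) # 1..5
}

#' Generate a synthetic three-level elemental knowledge graph
#'
#' The KG holds class nodes (e.g. `Nonmetals`, `ReactiveNonmetal`,
#' `Halogens`), chemical-level nodes (elements from a curated
#' mini-periodic-table and functional groups with literature SMARTS), and
#' property nodes (atomic-weight bins and periods). Hierarchy and property
#' triples are deterministic chemistry; the seed only drives the per-entity
#' attribute vectors used as two-hop edge features.
#'
#' @param n_elements number of elements, 2..10, taken in the order
#'   H, C, N, O, F, S, Cl, P, Br, I.
#' @param n_fgroups number of functional groups, 1..11 (Acetal first).
#' @param seed integer seed for the attribute vectors.
#' @return an `element_kg`.
#' @export
gen_element_kg <- function(n_elements = 10L, n_fgroups = 11L, seed = 1L) {
  n_elements <- assert_count(n_elements, "n_elements", min = 2L)
  n_fgroups <- assert_count(n_fgroups, "n_fgroups", min = 1L)
  assert_that(n_elements <= nrow(PERIODIC_TABLE), "hmg_argument_error",
              sprintf("n_elements must be <= %d", nrow(PERIODIC_TABLE)))
  assert_that(n_fgroups <= nrow(FUNCTIONAL_GROUPS), "hmg_argument_error",
              sprintf("n_fgroups must be <= %d", nrow(FUNCTIONAL_GROUPS)))

  els <- PERIODIC_TABLE[seq_len(n_elements), ]
  fgs <- FUNCTIONAL_GROUPS[seq_len(n_fgroups), ]
  classes <- unique(c("Nonmetals", ELEMENT_CLASSES$class[
    ELEMENT_CLASSES$symbol %in% els$symbol]))
  wbins <- paste0("Weight", sort(unique(weight_bin(els$weight))))
  periods <- paste0("Period", sort(unique(els$period)))

  entities <- rbind(
    data.frame(id = classes, level = "class", kind = "class",
               symbol = NA_character_, smarts = NA_character_),
    data.frame(id = els$symbol, level = "chemical", kind = "element",
               symbol = els$symbol, smarts = NA_character_),
    data.frame(id = fgs$name, level = "chemical", kind = "functional_group",
               symbol = NA_character_, smarts = fgs$smarts),
    data.frame(id = c(wbins, periods), level = "property", kind = "property",
               symbol = NA_character_, smarts = NA_character_)
  )

  cls <- ELEMENT_CLASSES$class[match(els$symbol, ELEMENT_CLASSES$symbol)]
  triples <- rbind(
    data.frame(head = setdiff(classes, "Nonmetals"), relation = "isSubClassOf",
               tail = "Nonmetals"),
    data.frame(head = els$symbol, relation = "isSubClassOf", tail = cls),
    do.call(rbind, lapply(seq_len(nrow(fgs)), function(k) {
      members <- intersect(strsplit(fgs$elements[k], ",")[[1]], els$symbol)
      if (length(members) == 0) return(NULL)
      data.frame(head = members, relation = "isPartOf", tail = fgs$name[k])
    })),
    data.frame(head = els$symbol, relation = "hasWeight",
               tail = paste0("Weight", weight_bin(els$weight))),
    data.frame(head = els$symbol, relation = "isInPeriod",
               tail = paste0("Period", els$period))
  )
  rownames(triples) <- NULL
  triples <- triples[order(triples$relation, triples$head, triples$tail), ]
  rownames(triples) <- NULL

  attributes <- with_seed(seed, {
    ids <- sort(entities$id)
    m <- matrix(stats::rnorm(length(ids) * EKG_ATTR_DIM), nrow = length(ids),
                dimnames = list(ids, NULL))
    m / sqrt(rowSums(m^2))
  })

  new_element_kg(entities, ELEMENT_KG_RELATIONS, triples, attributes)
}

DRUG_KG_RELATIONS <- c("targets", "interactsWith", "treats", "involvedIn",
                       "causesSideEffect", "associatedWith")

.category_relation <- c(gene = "targets", compound = "interactsWith",
                        disease = "treats", process = "involvedIn",
                        "side-effect" = "causesSideEffect",
                        symptom = "associatedWith")

#' Generate a synthetic drug knowledge graph with entity embeddings
#'
#' Drug entities are linked to non-drug entities (genes, compounds,
#' diseases, processes, side effects, symptoms) by category-typed
#' relations; every entity carries a unit-norm embedding of dimension
#' `d_kg`. The embeddings are seeded random stand-ins for trained KG
#' embeddings; `set_drug_embeddings()` accepts an external table.
#'
#' @param n_drugs number of drug entities (>= 1).
#' @param n_other_entities number of non-drug entities (>= 1).
#' @param d_kg embedding dimension (>= 2).
#' @param seed integer seed.
#' @return a `drug_kg`.
#' @export
gen_drug_kg <- function(n_drugs = 10L, n_other_entities = 12L, d_kg = 8L,
                        seed = 1L) {
  n_drugs <- assert_count(n_drugs, "n_drugs", min = 1L)
  n_other <- assert_count(n_other_entities, "n_other_entities", min = 0L)
  d_kg <- assert_count(d_kg, "d_kg", min = 2L)
  assert_that(n_other >= 1L, "hmg_argument_error",
              "a drug must connect to something: n_other_entities >= 1")

  drug_ids <- pad_id("DRUG", seq_len(n_drugs))
  other_cat <- rep(setdiff(DRUG_KG_CATEGORIES, "drug"), length.out = n_other)
  other_ids <- paste0(toupper(substr(other_cat, 1, 3)),
                      sprintf("%04d", seq_len(n_other)))
  entities <- rbind(
    data.frame(id = drug_ids, category = "drug"),
    data.frame(id = other_ids, category = other_cat)
  )

  triples <- with_seed(seed, {
    per_drug <- lapply(drug_ids, function(d) {
      k <- min(n_other, 2L)
      idx <- sample.int(n_other, k)
      data.frame(head = d, relation = unname(.category_relation[other_cat[idx]]),
                 tail = other_ids[idx])
    })
    do.call(rbind, per_drug)
  })
  rownames(triples) <- NULL

  embeddings <- with_seed(seed + 1L, {
    ids <- c(drug_ids, other_ids)
    m <- matrix(stats::rnorm(length(ids) * d_kg), nrow = length(ids),
                dimnames = list(ids, NULL))
    m / sqrt(rowSums(m^2))
  })

  new_drug_kg(entities, DRUG_KG_RELATIONS, triples, embeddings)
}

# Template chemistry for molecule pools: cores that accept one trailing
# substituent, chosen so the pool spans aromatic rings, halogens, esters,
# amides, nitriles, ethers and sulfonamides (some BRICS-cleavable, some not).
MOL_CORES <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "CCCC",
               "CC(C)C", "CCOCC")
MOL_SUBS <- c("", "C", "CC", "Cl", "F", "OC", "N", "C#N", "C(=O)OC",
              "C(=O)NC", "S(=O)(=O)N", "C(=O)C", "OC(=O)C")

#' Generate a seeded molecule pool with sparse drug annotations
#'
#' SMILES are composed from an internal template set (core plus
#' substituent). The first pool entry is always benzene (a single-BRICS-
#' fragment molecule) and, when `n_total >= 2`, the second is methyl
#' acetate (BRICS-cleavable), so fragmentation-dependent code paths are
#' always exercised. Exactly `ceiling(n_total * drug_fraction)` records are
#' assigned drug ids drawn from `dkg`, at seeded random positions.
#'
#' @param n_total pool size (>= 1).
#' @param drug_fraction fraction of records carrying a drug id, in `[0, 1]`.
#' @param dkg a `drug_kg` supplying drug entity ids.
#' @param seed integer seed.
#' @param allow_repeat_drug_ids if `TRUE`, drug ids may repeat when the pool
#'   needs more drug records than the KG has drugs.
#' @return a `molecule_pool` data frame with columns `smiles`, `drug_id`
#'   (`NA` when absent).
#' @export
gen_molecule_pool <- function(n_total, drug_fraction = 0.3, dkg, seed = 1L,
                              allow_repeat_drug_ids = FALSE) {
  n_total <- assert_count(n_total, "n_total", min = 1L)
  drug_fraction <- assert_fraction(drug_fraction, "drug_fraction")
  n_drug <- as.integer(ceiling(n_total * drug_fraction))
  drugs <- drug_entities(dkg)
  if (n_drug > length(drugs) && !allow_repeat_drug_ids) {
    hmg_error("hmg_argument_error",
              sprintf(paste0("need %d drug records but the drug KG has only ",
                             "%d drugs; set allow_repeat_drug_ids = TRUE"),
                      n_drug, length(drugs)))
  }
  with_seed(seed, {
    smiles <- character(n_total)
    smiles[1] <- "c1ccccc1"
    if (n_total >= 2) smiles[2] <- "CC(=O)OC"
    if (n_total >= 3) {
      k <- n_total - 2L
      smiles[3:n_total] <- paste0(sample(MOL_CORES, k, replace = TRUE),
                                  sample(MOL_SUBS, k, replace = TRUE))
    }
    drug_id <- rep(NA_character_, n_total)
    if (n_drug > 0) {
      pos <- sample.int(n_total, n_drug)
      drug_id[pos] <- sample(drugs, n_drug,
                             replace = n_drug > length(drugs))
    }
    structure(data.frame(smiles = smiles, drug_id = drug_id,
                         stringsAsFactors = FALSE),
              class = c("molecule_pool", "data.frame"))
  })
}
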