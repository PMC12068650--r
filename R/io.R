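# File formats and configuration: molecule CSV, KG TSVs (triples,
# attributes, embeddings), run configuration, JSON-lines logging. All
# writers emit a schema-version field that readers verify.

MOL_CSV_VERSION <- "molpool/1"
KG_TSV_VERSION <- "kgtsv/1"

#' Read molecule records from CSV
#'
#' The CSV needs a `smiles` column; `drug_id` is optional. Invalid SMILES
#' rows are collected into an error report: strict mode aborts naming the
#' first offending row, lenient mode skips them with a warning.
#'
#' @param path CSV file path.
#' @param strict abort on the first invalid SMILES (default `FALSE`).
#' @return a `molecule_pool` data frame with attribute `skipped` (row
#'   numbers of dropped records, lenient mode).
#' @export
read_molecules <- function(path, strict = FALSE) {
  assert_that(file.exists(path), "hmg_format_error",
              sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  assert_that("smiles" %in% names(df), "hmg_format_error",
              sprintf("%s: missing required column 'smiles'", path))
  if (!"drug_id" %in% names(df)) df$drug_id <- NA_character_
  df$drug_id[!nzchar(df$drug_id %||% "") | is.na(df$drug_id)] <- NA_character_
  ok <- unname(vapply(df$smiles, smiles_is_valid, logical(1)))
  if (!all(ok)) {
    bad <- which(!ok)
    if (strict) {
      hmg_error("hmg_parse_error",
                sprintf("%s: invalid SMILES at data row %d ('%s')",
                        path, bad[1], df$smiles[bad[1]]))
    }
    hmg_warn("hmg_skipped_rows",
             sprintf("%s: skipped %d invalid SMILES row(s): %s", path,
                     length(bad), paste(bad, collapse = ",")))
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  out <- structure(df[, c("smiles", "drug_id"), drop = FALSE],
                   class = c("molecule_pool", "data.frame"))
  attr(out, "skipped") <- if (all(ok)) integer(0) else which(!ok)
  out
}

#' Write molecule records to CSV
#' @param pool a `molecule_pool`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(pool, path) {
  utils::write.csv(as.data.frame(pool)[, c("smiles", "drug_id")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

.write_tsv <- function(df, path, version) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# schema: %s", version), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.read_tsv <- function(path, version) {
  assert_that(file.exists(path), "hmg_format_error",
              sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  got <- sub("^# schema: ", "", first)
  if (!identical(got, version)) {
    hmg_error("hmg_version_error",
              sprintf("%s: schema '%s', expected '%s'", path, got, version))
  }
  utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Write a knowledge graph to TSV files
#'
#' Triples go to `<stem>_triples.tsv` (head, relation, tail), entity
#' records to `<stem>_entities.tsv`, and numeric vectors (element-KG
#' attributes or drug-KG embeddings) to `<stem>_vectors.tsv` (id + values).
#' @param kg an `element_kg` or `drug_kg`.
#' @param stem output path stem.
#' @return the three paths, invisibly.
#' @export
write_kg <- function(kg, stem) {
  vec <- if (inherits(kg, "element_kg")) kg$attributes else kg$embeddings
  vdf <- data.frame(id = rownames(vec), vec, check.names = FALSE)
  names(vdf) <- c("id", paste0("v", seq_len(ncol(vec))))
  paths <- c(triples = paste0(stem, "_triples.tsv"),
             entities = paste0(stem, "_entities.tsv"),
             vectors = paste0(stem, "_vectors.tsv"))
  .write_tsv(kg$triples, paths["triples"], KG_TSV_VERSION)
  ent <- kg$entities
  ent$.kg_kind <- if (inherits(kg, "element_kg")) "element" else "drug"
  ent$.relations <- paste(kg$relations, collapse = ",")
  .write_tsv(ent, paths["entities"], KG_TSV_VERSION)
  .write_tsv(vdf, paths["vectors"], KG_TSV_VERSION)
  invisible(paths)
}

#' Read a knowledge graph from TSV files written by [write_kg()]
#'
#' Referential integrity is enforced on load; vector widths must be
#' constant (the reader fails on ragged rows).
#' @param stem path stem used at write time.
#' @return an `element_kg` or `drug_kg`.
#' @export
read_kg <- function(stem) {
  triples <- .read_tsv(paste0(stem, "_triples.tsv"), KG_TSV_VERSION)
  ent <- .read_tsv(paste0(stem, "_entities.tsv"), KG_TSV_VERSION)
  vdf <- .read_tsv(paste0(stem, "_vectors.tsv"), KG_TSV_VERSION)
  if (anyNA(as.matrix(vdf[, -1, drop = FALSE]))) {
    hmg_error("hmg_format_error", "ragged or non-numeric vector rows")
  }
  vec <- as.matrix(vdf[, -1, drop = FALSE])
  rownames(vec) <- vdf$id
  colnames(vec) <- NULL
  kind <- ent$.kg_kind[1]
  relations <- strsplit(ent$.relations[1], ",", fixed = TRUE)[[1]]
  ent$.kg_kind <- NULL; ent$.relations <- NULL
  if (kind == "element") {
    new_element_kg(ent, relations, triples, vec)
  } else {
    new_drug_kg(ent, relations, triples, vec)
  }
}

#' Run configuration with validated keys
#'
#' Central tunables: encoder width `d`, heads `K`, layers `L`, pooling
#' ratio `r`, temperature `tau`, batch size `N`, random complement `n`,
#' learning rate `lr`, `epochs`, `seed`, drug-KG dimension `d_kg`.
#' Unknown keys are rejected.
#' @param ... overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(d = 16L, K = 4L, L = 2L, r = 0.5, tau = 0.1, N = 10L,
                   n = 1L, lr = 1e-3, epochs = 50L, seed = 1L, d_kg = 8L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    hmg_error("hmg_format_error",
              sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ",")))
  }
  cfg <- utils::modifyList(defaults, over)
  assert_that(cfg$d %% cfg$K == 0, "hmg_argument_error",
              "d must be divisible by K")
  assert_that(cfg$tau > 0, "hmg_argument_error", "tau must be > 0")
  assert_that(cfg$n <= ceiling(0.3 * cfg$N), "hmg_argument_error",
              "n must be <= ceiling(0.3 N)")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a JSON file
#' @param path JSON file whose keys are [run_config()] keys.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

#' Append a structured record to a JSON-lines log
#' @param record named list.
#' @param path log file path (created if missing).
#' @return `path`, invisibly.
#' @export
log_jsonl <- function(record, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

ENC_CKPT_VERSION <- "hmgenc/1"

# order-insensitive fingerprint of the raw feature schema, so checkpoints
# refuse to load against a package whose feature tables changed
feature_schema_hash <- function(d_kg) {
  dims <- hmg_feature_dims(d_kg)
  paste0("fs", sum(c(dims$node, dims$edge) *
                     seq_along(c(dims$node, dims$edge))), "k", dims$k_pos)
}

#' Write encoder parameters to a JSON checkpoint
#'
#' A single JSON document: a header (`d`, `K`, `L`, `r`, `d_kg`, LeakyReLU
#' slope, schema version and a feature-schema hash) plus every parameter
#' matrix under its dotted path name (e.g. `layers.l1.WQ.2`, `A.atom`).
#' @param params an `encoder_params`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(params, path) {
  flat <- flatten_params(params)
  obj <- list(
    schema = ENC_CKPT_VERSION,
    header = list(d = params$d, K = params$K, L = params$L, r = params$r,
                  d_kg = params$d_kg, leak = params$leak,
                  feature_schema = feature_schema_hash(params$d_kg)),
    params = lapply(flat, function(m)
      list(dim = dim(m), data = as.numeric(m)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read encoder parameters from a JSON checkpoint
#' @param path file written by [write_checkpoint()].
#' @return an `encoder_params`.
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, ENC_CKPT_VERSION)) {
    hmg_error("hmg_version_error",
              sprintf("checkpoint schema '%s', expected '%s'",
                      obj$schema %||% "<none>", ENC_CKPT_VERSION))
  }
  h <- obj$header
  if (!identical(h$feature_schema, feature_schema_hash(h$d_kg))) {
    hmg_error("hmg_version_error",
              "checkpoint feature schema does not match this package")
  }
  template <- encoder_params(d = h$d, K = h$K, L = h$L, r = h$r,
                             d_kg = h$d_kg, leak = h$leak, seed = 1L)
  flat <- lapply(obj$params, function(p)
    matrix(as.numeric(p$data), p$dim[1], p$dim[2]))
  missing <- setdiff(names(flatten_params(template)), names(flat))
  if (length(missing) > 0) {
    hmg_error("hmg_format_error",
              sprintf("checkpoint missing parameter(s): %s",
                      paste(utils::head(missing, 3), collapse = ",")))
  }
  unflatten_params(template, flat)
}
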