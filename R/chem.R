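# SMILES parsing and substructure utilities built on ChemmineR / Open Babel.
#
# Connectivity, bond orders and atom order come from Open Babel's SDF
# conversion (which preserves SMILES atom order); aromatic flags and formal
# charges are recovered from the SMILES atom tokens, since the SDF block is
# kekulized. Hydrogens are implicit throughout (heavy-atom graph).

PERIODIC_TABLE <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "S", "Cl", "P", "Br", "I"),
  weight = c(1.008, 12.011, 14.007, 15.999, 18.998, 32.06, 35.45,
             30.974, 79.904, 126.904),
  period = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 5L),
  stringsAsFactors = FALSE
)

# Tokenize the atoms of a SMILES string in order, returning per-atom
# aromaticity and formal charge. Ring-closure digits, branches and bond
# symbols are skipped; bracket atoms are parsed for symbol/charge.
scan_smiles_atoms <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  syms <- character(0); arom <- logical(0); chg <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) hmg_error("hmg_parse_error",
                           sprintf("unbalanced bracket in SMILES: %s", smiles))
      tok <- paste(chars[(i + 1):(j - 1)], collapse = "")
      m <- regexec("^[0-9]*([A-Za-z][a-z]?)", tok)
      sym <- regmatches(tok, m)[[1]][2]
      if (is.na(sym)) hmg_error("hmg_parse_error",
                                sprintf("cannot read bracket atom '[%s]'", tok))
      is_arom <- substr(sym, 1, 1) %in% letters
      # trailing H<count> inside a bracket is an H-count, not an atom
      if (nchar(sym) == 2 && substr(sym, 2, 2) == "H" &&
          toupper(substr(sym, 1, 1)) != "C") {
        sym <- substr(sym, 1, 1)
      }
      cm <- regmatches(tok, regexec("([+-])([0-9]*)([+-]*)$", tok))[[1]]
      charge <- 0L
      if (length(cm) == 4 && nzchar(cm[2])) {
        sgn <- if (cm[2] == "+") 1L else -1L
        charge <- if (nzchar(cm[3])) sgn * as.integer(cm[3]) else
          sgn * (1L + nchar(cm[4]))
      }
      s <- if (is_arom) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2)) else sym
      syms <- c(syms, s); arom <- c(arom, is_arom); chg <- c(chg, charge)
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      if (i < n && paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
        syms <- c(syms, paste0(ch, chars[i + 1]))
        i <- i + 2L
      } else {
        syms <- c(syms, ch)
        i <- i + 1L
      }
      arom <- c(arom, FALSE); chg <- c(chg, 0L)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      syms <- c(syms, toupper(ch)); arom <- c(arom, TRUE); chg <- c(chg, 0L)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "(", ")", ".",
                         "%", "@", "+", as.character(0:9))) {
      i <- i + 1L
    } else {
      hmg_error("hmg_parse_error",
                sprintf("unexpected character '%s' in SMILES: %s", ch, smiles))
    }
  }
  data.frame(symbol = syms, aromatic = arom, charge = chg,
             stringsAsFactors = FALSE)
}

#' Parse a SMILES string into an annotated molecular graph
#'
#' Connectivity and kekulized bond orders are obtained through Open Babel;
#' aromatic flags and formal charges come from the SMILES atom tokens. Ring
#' membership is derived from the bond graph (a bond is in a ring iff it is
#' not a bridge), and hybridization is assigned from the bond pattern
#' (sp: triple bond or two double bonds; sp2: aromatic or one double bond;
#' otherwise sp3).
#'
#' @param smiles a single SMILES string.
#' @return an object of class `hmg_mol`: a list with `smiles`, an `atoms`
#'   data frame (`symbol`, `aromatic`, `charge`, `degree`, `in_ring`,
#'   `hybrid`) and a `bonds` data frame (`i`, `j`, `order`, `aromatic`,
#'   `in_ring`, `conjugated`), 1-based atom indices.
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    hmg_error("hmg_parse_error",
              sprintf("invalid SMILES input: '%s'", paste(smiles, collapse = ",")))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) hmg_error(
      "hmg_parse_error", sprintf("cannot parse SMILES '%s': %s", smiles,
                                 conditionMessage(e)))
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  n_atoms <- nrow(ab)
  if (is.null(n_atoms) || n_atoms < 1) {
    hmg_error("hmg_parse_error", sprintf("SMILES '%s' has no atoms", smiles))
  }
  symbols <- sub("_[0-9]+$", "", rownames(ab))
  toks <- scan_smiles_atoms(smiles)
  if (nrow(toks) != n_atoms || !all(toks$symbol == symbols)) {
    hmg_error("hmg_parse_error",
              sprintf("unsupported SMILES features in '%s' (atom-token mismatch)",
                      smiles))
  }
  if (!all(symbols %in% PERIODIC_TABLE$symbol)) {
    bad <- setdiff(unique(symbols), PERIODIC_TABLE$symbol)
    hmg_error("hmg_parse_error",
              sprintf("element(s) outside supported table in '%s': %s",
                      smiles, paste(bad, collapse = ",")))
  }

  if (is.null(dim(bb)) || length(bb) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bb <- matrix(as.integer(bb), ncol = ncol(bb),
                 dimnames = list(NULL, colnames(bb)))
    bonds <- data.frame(i = bb[, 1], j = bb[, 2], order = bb[, 3])
  }

  in_ring_bond <- rep(FALSE, nrow(bonds))
  in_ring_atom <- rep(FALSE, n_atoms)
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_atoms - igraph::vcount(g)))
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    ring_atoms <- unique(c(bonds$i[in_ring_bond], bonds$j[in_ring_bond]))
    in_ring_atom[ring_atoms] <- TRUE
  }

  degree <- tabulate(c(bonds$i, bonds$j), nbins = n_atoms)
  n_double <- tabulate(c(bonds$i[bonds$order == 2], bonds$j[bonds$order == 2]),
                       nbins = n_atoms)
  n_triple <- tabulate(c(bonds$i[bonds$order == 3], bonds$j[bonds$order == 3]),
                       nbins = n_atoms)
  hybrid <- ifelse(n_triple > 0 | n_double >= 2, "sp",
                   ifelse(toks$aromatic | n_double == 1, "sp2", "sp3"))

  bond_arom <- toks$aromatic[bonds$i] & toks$aromatic[bonds$j] & in_ring_bond
  sp2ish <- hybrid %in% c("sp", "sp2")
  conj <- sp2ish[bonds$i] & sp2ish[bonds$j]

  structure(list(
    smiles = smiles,
    atoms = data.frame(symbol = symbols, aromatic = toks$aromatic,
                       charge = toks$charge, degree = degree,
                       in_ring = in_ring_atom, hybrid = hybrid,
                       stringsAsFactors = FALSE),
    bonds = data.frame(i = bonds$i, j = bonds$j, order = bonds$order,
                       aromatic = bond_arom, in_ring = in_ring_bond,
                       conjugated = conj)
  ), class = "hmg_mol")
}

#' Test whether a SMILES string parses
#' @param smiles a single SMILES string.
#' @return `TRUE` or `FALSE`.
#' @export
smiles_is_valid <- function(smiles) {
  !inherits(tryCatch(parse_smiles(smiles), error = identity), "error")
}

# Render an (optionally atom-induced) subgraph of an hmg_mol as a V2000 MOL
# block. Bond orders stay kekulized; Open Babel re-perceives aromaticity and
# implicit hydrogens on read, so SMARTS H-counts work on the result.
mol_to_molblock <- function(mol, atom_subset = NULL) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  if (!is.null(atom_subset)) {
    atom_subset <- sort(unique(as.integer(atom_subset)))
    keep <- bonds$i %in% atom_subset & bonds$j %in% atom_subset
    bonds <- bonds[keep, , drop = FALSE]
    remap <- integer(nrow(atoms)); remap[atom_subset] <- seq_along(atom_subset)
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    atoms <- atoms[atom_subset, , drop = FALSE]
  }
  na <- nrow(atoms); nb <- nrow(bonds)
  header <- sprintf("fragment\n  hmglearn\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    na, nb)
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    atoms$symbol)
  bond_lines <- if (nb > 0) {
    sprintf("%3d%3d%3d  0", bonds$i, bonds$j, bonds$order)
  } else character(0)
  chg <- which(atoms$charge != 0)
  chg_lines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf(" %3d %3d", chg, atoms$charge[chg]), collapse = ""))
  } else character(0)
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", "$$$$", ""),
        collapse = "\n")
}

# Number of matches of a SMARTS pattern in a molecule or atom-induced
# fragment subgraph (Open Babel match count; 0 means no match).
smarts_match_count <- function(mol, smarts, atom_subset = NULL) {
  block <- mol_to_molblock(mol, atom_subset)
  refs <- ChemmineOB::forEachMol("SDF", block, identity)
  as.integer(ChemmineOB::smartsSearch_OB(refs, smarts, uniqueMatches = TRUE))
}

#' Check that a SMARTS pattern is syntactically usable
#'
#' The pattern is compiled by Open Babel against a probe molecule; invalid
#' patterns fail to match anything and raise a parse warning inside Open
#' Babel, which is surfaced here as `FALSE`.
#' @param smarts a single SMARTS string.
#' @return `TRUE` if the pattern compiles.
#' @export
smarts_is_valid <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1L || !nzchar(smarts)) {
    return(FALSE)
  }
  probe <- parse_smiles("OC(O)CC(=O)OCN")
  res <- tryCatch(
    suppressWarnings(smarts_match_count(probe, smarts)),
    error = function(e) NA_integer_
  )
  !is.na(res)
}

#' Folded circular fingerprints for a set of SMILES
#'
#' Radius-2 circular (ECFP4) fingerprints from Open Babel, folded from 4096
#' to `nbits` bits by OR-ing blocks. Deterministic in the input.
#'
#' @param smiles_vec character vector of SMILES.
#' @param nbits fingerprint width after folding (default 1024).
#' @return a binary matrix with one row per molecule.
#' @export
mol_fingerprints <- function(smiles_vec, nbits = 1024L) {
  if (length(smiles_vec) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = nbits))
  }
  rows <- lapply(seq_along(smiles_vec), function(idx) {
    smi <- smiles_vec[idx]
    if (!smiles_is_valid(smi)) {
      hmg_error("hmg_parse_error",
                sprintf("record %d: invalid SMILES '%s'", idx, smi))
    }
    refs <- ChemmineOB::forEachMol("SMILES", smi, identity)
    fp <- ChemmineOB::fingerprint_OB(refs, "ECFP4")
    fp <- as.numeric(fp)
    folds <- matrix(fp, nrow = nbits)
    as.numeric(rowSums(folds) > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
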