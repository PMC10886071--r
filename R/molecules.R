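## SMILES parsing and canonicalization on top of openbabel (ChemmineOB).
## openbabel repairs some malformed inputs silently, so a lexical pre-check
## rejects the classic failure modes (unbalanced parentheses / ring bonds,
## illegal characters) before conversion.

#' Categorical vocabularies of the molecular-graph featurization
#'
#' Fixed enumerations shipped with the package; categories outside the
#' vocabulary map to the `"UNK"` bucket instead of erroring, so unusual
#' chemistry degrades gracefully.
#'
#' @return named list of character vectors: `atomTypes`, `chirality`,
#'   `bondTypes`, `bondDirections`, each ending in `"UNK"`.
#' @export
moleculeVocab <- function() {
  list(
    atomTypes = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
                  "Si", "Se", "Na", "K", "Li", "Ca", "Mg", "Zn", "Fe",
                  "H", "UNK"),
    chirality = c("none", "cw", "ccw", "UNK"),
    bondTypes = c("single", "double", "triple", "aromatic", "UNK"),
    bondDirections = c("none", "up", "down", "UNK")
  )
}

#' The amino-acid alphabet used by [ProteinSequence-class]
#'
#' The 20 standard residues plus the explicit unknown symbol `X`.
#'
#' @return character vector of single letters.
#' @export
aminoAcidAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

## Lexical sanity check: balanced (), every ring-bond digit opened and
## closed, bracket atoms closed, characters from the SMILES alphabet.
validateSmilesLexically <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("SMILES must be a single nonempty string")
  if (grepl("[[:space:]]", smiles))
    stop("invalid SMILES '", smiles, "': whitespace not allowed")
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", smiles))
    stop("invalid SMILES '", smiles, "': illegal character")
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  inBracket <- FALSE
  ring <- integer()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (inBracket) {
      if (ch == "]") inBracket <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "[") inBracket <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("invalid SMILES '", smiles, "': unbalanced parenthesis")
    } else if (grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      ring[as.character(d)] <- if (is.na(ring[as.character(d)])) 1L
                               else NA_integer_
      ring <- ring[!is.na(ring)]
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$",
                               paste0(chars[i + 1L], chars[i + 2L])))
        stop("invalid SMILES '", smiles, "': malformed %nn ring bond")
      d <- paste0(chars[i + 1L], chars[i + 2L])
      ring[d] <- if (is.na(ring[d])) 1L else NA_integer_
      ring <- ring[!is.na(ring)]
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (inBracket) stop("invalid SMILES '", smiles, "': unclosed bracket atom")
  if (depth != 0L)
    stop("invalid SMILES '", smiles, "': unbalanced parenthesis")
  if (length(ring))
    stop("invalid SMILES '", smiles, "': unmatched ring bond")
  invisible(TRUE)
}

## Per-atom chirality tags in SMILES order. openbabel preserves input atom
## order in SMI->SDF conversion, so these align with the molblock atoms.
smilesAtomChirality <- function(smiles) {
  out <- character()
  chars <- strsplit(smiles, "")[[1]]
  i <- 1L
  n <- length(chars)
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      tok <- paste(chars[i:j], collapse = "")
      chir <- if (grepl("@@", tok)) "cw" else if (grepl("@", tok)) "ccw"
              else "none"
      out <- c(out, chir)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n &&
               chars[i + 1L] %in% c("l", "r")) {
      out <- c(out, "none")   # Cl / Br
      i <- i + 2L
    } else if (ch %in% organic || ch %in% c("b", "c", "n", "o", "p", "s")) {
      out <- c(out, "none")
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Canonical SMILES of a molecule
#'
#' Deterministic canonical form produced by the openbabel canonicalization;
#' used as the drug key of the knowledge store so that chemically identical
#' spellings resolve to the same entity.
#'
#' @param smiles a single SMILES string.
#' @return canonical SMILES string.
#' @export
canonicalSmiles <- function(smiles) {
  validateSmilesLexically(smiles)
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles)
  )
  out <- trimws(strsplit(out, "[\t\n]")[[1]][1])
  if (is.na(out) || !nzchar(out))
    stop("invalid SMILES '", smiles, "': cannot be parsed")
  out
}

#' Parse a SMILES string into a [MolecularGraph-class]
#'
#' Atoms carry type and chirality categories; bonds carry bond type and
#' bond direction categories (vocabularies from [moleculeVocab()]).
#' Invalid SMILES raise a parse error naming the offending input.
#'
#' @param smiles a single nonempty SMILES string.
#' @return a [MolecularGraph-class].
#' @examples
#' parseMolecule("CCO")
#' @export
parseMolecule <- function(smiles) {
  validateSmilesLexically(smiles)
  canon <- canonicalSmiles(smiles)
  mb <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles)
  )
  ln <- strsplit(mb, "\n", fixed = TRUE)[[1]]
  counts <- ln[4]
  nAtoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nBonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nAtoms) || nAtoms < 1L)
    stop("invalid SMILES '", smiles, "': no atoms parsed")
  atomLines <- ln[5:(4 + nAtoms)]
  els <- vapply(atomLines, function(x) trimws(substr(x, 32, 34)), "",
                USE.NAMES = FALSE)
  chir <- smilesAtomChirality(smiles)
  if (length(chir) != nAtoms) chir <- rep("none", nAtoms)  # lexer fallback
  vocab <- moleculeVocab()
  atomType <- ifelse(els %in% vocab$atomTypes, els, "UNK")
  chir <- ifelse(chir %in% vocab$chirality, chir, "UNK")
  if (nBonds > 0L) {
    bondLines <- ln[(5 + nAtoms):(4 + nAtoms + nBonds)]
    u <- as.integer(substr(bondLines, 1, 3))
    v <- as.integer(substr(bondLines, 4, 6))
    ord <- as.integer(substr(bondLines, 7, 9))
    st <- suppressWarnings(as.integer(substr(bondLines, 10, 12)))
    btype <- c("single", "double", "triple", "aromatic")[
      pmin(pmax(ord, 1L), 4L)]
    btype[is.na(btype)] <- "UNK"
    bdir <- rep("none", nBonds)
    bdir[!is.na(st) & st == 1L] <- "up"
    bdir[!is.na(st) & st == 6L] <- "down"
    bondsDf <- data.frame(u = u, v = v, type = btype, direction = bdir,
                          stringsAsFactors = FALSE)
  } else {
    bondsDf <- data.frame(u = integer(), v = integer(),
                          type = character(), direction = character(),
                          stringsAsFactors = FALSE)
  }
  new("MolecularGraph",
      atoms = data.frame(type = atomType, chirality = chir,
                         stringsAsFactors = FALSE),
      bonds = bondsDf,
      sourceSmiles = smiles,
      canonicalKey = canon)
}

#' Bemis-Murcko scaffold key of a molecule
#'
#' The scaffold is the ring-system-plus-linker framework obtained by
#' iteratively pruning terminal (degree-1) atoms. The key is a canonical
#' serialization of the remaining colored graph (atom elements as vertex
#' colors, bond orders ignored, BLISS canonical labeling), so any two
#' molecules sharing a framework share a key. Acyclic molecules have an
#' empty scaffold and return `""`; they are grouped together by
#' [scaffoldSplit()].
#'
#' @param mol a [MolecularGraph-class] or SMILES string.
#' @return a character scaffold key (possibly `""`).
#' @export
scaffoldKey <- function(mol) {
  if (is.character(mol)) mol <- parseMolecule(mol)
  stopifnot(is(mol, "MolecularGraph"))
  a <- atoms(mol)
  b <- bonds(mol)
  keep <- rep(TRUE, nrow(a))
  repeat {
    deg <- integer(nrow(a))
    act <- b[keep[b$u] & keep[b$v], , drop = FALSE]
    if (nrow(act)) {
      tb <- table(factor(c(act$u, act$v), levels = seq_len(nrow(a))))
      deg <- as.integer(tb)
    }
    terminal <- keep & deg <= 1L
    if (!any(terminal)) break
    keep[terminal] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) return("")
  idx <- which(keep)
  remap <- match(seq_len(nrow(a)), idx)
  act <- b[keep[b$u] & keep[b$v], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(remap[act$u], remap[act$v]))
  cols <- as.integer(factor(a$type[idx], levels = moleculeVocab()$atomTypes))
  cp <- igraph::canonical_permutation(g, colors = cols)
  gp <- igraph::permute(g, cp$labeling)
  colsP <- integer(length(idx))
  colsP[cp$labeling] <- cols
  el <- igraph::as_edgelist(gp)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("a:", paste(colsP, collapse = ","),
         ";e:", paste(paste(el[, 1], el[, 2], sep = "-"), collapse = ","))
}
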