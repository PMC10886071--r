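## Readers/writers for the standard formats the framework touches:
## FASTA (proteins), TSV triplets (knowledge base), JSONL (texts),
## CSV (task tables), plus the knowledge-store directory layout.

#' Construct a ProteinSequence
#'
#' @param id sequence identifier.
#' @param residues amino-acid string; uppercased; characters outside the
#'   standard alphabet are replaced by the unknown symbol `X`.
#' @return a [ProteinSequence-class].
#' @export
proteinSequence <- function(id, residues) {
  r <- toupper(residues)
  chars <- strsplit(r, "")[[1]]
  chars[!chars %in% aminoAcidAlphabet()] <- "X"
  new("ProteinSequence", id = as.character(id),
      residues = paste(chars, collapse = ""))
}

#' Read protein sequences from a FASTA file
#'
#' One [ProteinSequence-class] per record; the id is the first whitespace
#' token of the header and sequences are uppercased.
#'
#' @param path FASTA file path.
#' @return list of [ProteinSequence-class].
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    stop("FASTA format error in ", path, ": ",
                         conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: ", path, " is empty")
  if (any(Biostrings::width(set) == 0L))
    stop("FASTA format error: record with empty sequence in ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  lapply(seq_along(set), function(i)
    proteinSequence(ids[i], as.character(set[[i]])))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins list of [ProteinSequence-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaProteins <- function(proteins, path) {
  set <- Biostrings::AAStringSet(vapply(proteins, residues, ""))
  names(set) <- vapply(proteins, seqId, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a KnowledgeBase from triplets
#'
#' Entities are the union of heads and tails in first-appearance order
#' (heads and tails interleaved row by row); duplicate triplets are
#' removed. Entity order is stable and defines embedding row order.
#'
#' @param h,r,t character vectors: head entity, relation label, tail entity.
#' @param entities optional explicit entity universe (superset of heads and
#'   tails, order preserved).
#' @return a [KnowledgeBase-class].
#' @export
knowledgeBase <- function(h = character(), r = character(),
                          t = character(), entities = NULL) {
  tr <- data.frame(h = as.character(h), r = as.character(r),
                   t = as.character(t), stringsAsFactors = FALSE)
  tr <- tr[!duplicated(tr), , drop = FALSE]
  rownames(tr) <- NULL
  ents <- if (is.null(entities)) {
    unique(as.vector(t(as.matrix(tr[, c("h", "t")]))))
  } else {
    unique(as.character(entities))
  }
  new("KnowledgeBase", entities = ents, triplets = tr)
}

#' Load a knowledge base from a TSV of (head, relation, tail) triplets
#'
#' The file must have three tab-separated columns; a header line
#' `head\\trelation\\ttail` is recognized and skipped. Malformed rows raise
#' a format error with the offending line number.
#'
#' @param path TSV file path.
#' @return a [KnowledgeBase-class].
#' @export
loadKnowledgeBase <- function(path) {
  if (!file.exists(path)) stop("triplet file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("triplet format error: ", path, " is empty")
  start <- 1L
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) == 3L &&
      identical(tolower(first), c("head", "relation", "tail")))
    start <- 2L
  if (start > length(lines))
    stop("triplet format error: ", path, " has a header but no rows")
  parts <- strsplit(lines[start:length(lines)], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("triplet format error in ", path, " at line ",
         start - 1L + bad[1], ": expected 3 tab-separated columns")
  m <- do.call(rbind, parts)
  knowledgeBase(h = m[, 1], r = m[, 2], t = m[, 3])
}

#' Write a knowledge base to triplet TSV
#'
#' @param kb a [KnowledgeBase-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, path) {
  tr <- triplets(kb)
  writeLines(c("head\trelation\ttail",
               paste(tr$h, tr$r, tr$t, sep = "\t")), path)
  invisible(path)
}

#' Read entity descriptions from JSONL
#'
#' One JSON object per line with fields `entity_id` and `text`.
#'
#' @param path JSONL file path.
#' @return data.frame with columns `entity_id`, `text`.
#' @export
readTextRecords <- function(path) {
  if (!file.exists(path)) stop("text file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop("JSONL format error at line ", i, ": ",
                           conditionMessage(e)))
    if (is.null(obj$entity_id))
      stop("JSONL format error at line ", i, ": missing entity_id")
    data.frame(entity_id = as.character(obj$entity_id),
               text = as.character(obj$text %||% ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write entity descriptions as JSONL
#'
#' @param texts named character vector (entity id -> text) or data.frame
#'   with columns `entity_id`, `text`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTextRecords <- function(texts, path) {
  if (is.data.frame(texts)) {
    ids <- texts$entity_id
    txt <- texts$text
  } else {
    ids <- names(texts)
    txt <- unname(texts)
  }
  lines <- vapply(seq_along(ids), function(i)
    jsonlite::toJSON(list(entity_id = ids[i], text = txt[i]),
                     auto_unbox = TRUE), "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a TaskTable
#'
#' @param task `"DTI"`, `"DP"`, `"DDI"` or `"PPI"`.
#' @param left,right structure keys (right absent for DP).
#' @param labels numeric vector or matrix of 0/1 labels; `NA` marks missing
#'   labels (multi-task DP only). Missing labels are excluded from the
#'   training loss.
#' @return a [TaskTable-class].
#' @export
taskTable <- function(task, left, right = NULL, labels) {
  if (!is.matrix(labels)) labels <- matrix(labels, ncol = 1L)
  new("TaskTable", task = task, left = as.character(left),
      right = if (is.null(right)) character() else as.character(right),
      labels = labels, nLabels = ncol(labels))
}

#' Read a labeled task table from CSV
#'
#' Expected columns: `left` (structure key), `right` (pair tasks only), and
#' either a single `label` column or multiple `label_*` columns (multi-task
#' DP / multi-label PPI). Empty cells become missing labels.
#'
#' @param path CSV path.
#' @param task task tag.
#' @return a [TaskTable-class].
#' @export
readTaskTable <- function(path, task) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"left" %in% names(df))
    stop("task table ", path, " must have a 'left' column")
  labCols <- grep("^label(_|$)", names(df), value = TRUE)
  if (!length(labCols))
    stop("task table ", path, " must have 'label' or 'label_*' columns")
  labels <- as.matrix(df[, labCols, drop = FALSE])
  storage.mode(labels) <- "double"
  taskTable(task, df$left,
            right = if (task == "DP") NULL else df$right,
            labels = labels)
}

#' Write a task table to CSV
#'
#' @param tab a [TaskTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaskTable <- function(tab, path) {
  keys <- taskKeys(tab)
  lab <- taskLabels(tab)
  colnames(lab) <- if (ncol(lab) == 1L) "label"
                   else paste0("label_", seq_len(ncol(lab)))
  df <- if (taskName(tab) == "DP") data.frame(left = keys$left)
        else data.frame(left = keys$left, right = keys$right)
  utils::write.csv(cbind(df, as.data.frame(lab)), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
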