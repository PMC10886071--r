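#' Accessors for moltriad classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... unused.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x, ...) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("canonicalKey", function(x, ...) standardGeneric("canonicalKey"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x, ...) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("seqId", function(x, ...) standardGeneric("seqId"))
#' @rdname accessors
#' @export
setGeneric("entities", function(x, ...) standardGeneric("entities"))
#' @rdname accessors
#' @export
setGeneric("triplets", function(x, ...) standardGeneric("triplets"))
#' @rdname accessors
#' @export
setGeneric("taskName", function(x, ...) standardGeneric("taskName"))
#' @rdname accessors
#' @export
setGeneric("taskLabels", function(x, ...) standardGeneric("taskLabels"))
#' @rdname accessors
#' @export
setGeneric("taskKeys", function(x, ...) standardGeneric("taskKeys"))
#' @rdname accessors
#' @export
setGeneric("embeddingMatrix", function(x, ...)
  standardGeneric("embeddingMatrix"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("folds", function(x, ...) standardGeneric("folds"))
#' @rdname accessors
#' @export
setGeneric("strategy", function(x, ...) standardGeneric("strategy"))
#' @rdname accessors
#' @export
setGeneric("corpusStore", function(x, ...) standardGeneric("corpusStore"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("storeKb", function(x, ...) standardGeneric("storeKb"))

#' @rdname accessors
#' @export
setMethod("atoms", "MolecularGraph", function(x, ...) x@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "MolecularGraph", function(x, ...) x@bonds)
#' @rdname accessors
#' @export
setMethod("canonicalKey", "MolecularGraph", function(x, ...) x@canonicalKey)
#' @rdname accessors
#' @export
setMethod("canonicalKey", "ProteinSequence", function(x, ...)
  toupper(x@residues))
#' @rdname accessors
#' @export
setMethod("residues", "ProteinSequence", function(x, ...) x@residues)
#' @rdname accessors
#' @export
setMethod("seqId", "ProteinSequence", function(x, ...) x@id)
#' @rdname accessors
#' @export
setMethod("entities", "KnowledgeBase", function(x, ...) x@entities)
#' @rdname accessors
#' @export
setMethod("triplets", "KnowledgeBase", function(x, ...) x@triplets)
#' @rdname accessors
#' @export
setMethod("taskName", "TaskTable", function(x, ...) x@task)
#' @rdname accessors
#' @export
setMethod("taskLabels", "TaskTable", function(x, ...) x@labels)
#' @rdname accessors
#' @export
setMethod("taskKeys", "TaskTable", function(x, ...)
  list(left = x@left, right = x@right))
#' @rdname accessors
#' @export
setMethod("embeddingMatrix", "KgEmbedding", function(x, ...) x@matrix)
#' @rdname accessors
#' @export
setMethod("provenance", "KgEmbedding", function(x, ...) x@provenance)
#' @rdname accessors
#' @export
setMethod("provenance", "SplitSpec", function(x, ...) x@provenance)
#' @rdname accessors
#' @export
setMethod("folds", "SplitSpec", function(x, ...) x@folds)
#' @rdname accessors
#' @export
setMethod("strategy", "SplitSpec", function(x, ...) x@strategy)
#' @rdname accessors
#' @export
setMethod("corpusStore", "SyntheticCorpus", function(x, ...) x@store)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticCorpus", function(x, ...) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("storeKb", "KnowledgeStore", function(x, ...) x@kb)

#' @describeIn accessors number of task rows
#' @export
setMethod("length", "TaskTable", function(x) length(x@left))

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", nrow(object@atoms), "atoms,",
      nrow(object@bonds), "bonds\n")
  cat("  canonical key:", object@canonicalKey, "\n")
})

setMethod("show", "ProteinSequence", function(object) {
  r <- object@residues
  cat("ProteinSequence", object@id, sprintf("(%d aa):", nchar(r)),
      if (nchar(r) > 40) paste0(substr(r, 1, 40), "...") else r, "\n")
})

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase:", length(object@entities), "entities,",
      nrow(object@triplets), "triplets,",
      length(unique(object@triplets$r)), "relation types\n")
})

setMethod("show", "TaskTable", function(object) {
  cat("TaskTable [", object@task, "]: ", length(object@left), " rows, ",
      object@nLabels, " label(s)\n", sep = "")
})

setMethod("show", "KgEmbedding", function(object) {
  cat("KgEmbedding:", nrow(object@matrix), "entities x",
      ncol(object@matrix), "dims\n")
  pv <- object@provenance
  if (!is.null(pv$seed))
    cat("  seed:", pv$seed, " propagation order:", pv$order, "\n")
})

setMethod("show", "KnowledgeStore", function(object) {
  cat("KnowledgeStore:", length(object@drugIndex), "drug keys,",
      length(object@proteinIndex), "protein keys,",
      length(object@texts), "texts\n")
})

setMethod("show", "SplitSpec", function(object) {
  cat("SplitSpec [", object@strategy, "]: ", length(object@folds),
      " fold(s), seed ", object@seed, "\n", sep = "")
})

setMethod("show", "SyntheticCorpus", function(object) {
  gt <- object@groundTruth
  cat("SyntheticCorpus:", sum(gt$kind == "drug"), "drugs,",
      sum(gt$kind == "protein"), "proteins,",
      length(unique(gt$community)), "communities\n")
})

setMethod("show", "MultimodalRecord", function(object) {
  cat("MultimodalRecord [", object@kind, "] entity=",
      ifelse(is.na(object@entityId), "<miss>", object@entityId),
      " sk=", object@skProvenance,
      " text=", ifelse(object@textPresent, "present", "absent"),
      "\n", sep = "")
})
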