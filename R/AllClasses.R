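#' @import methods
#' @importFrom stats rnorm runif rbinom sd quantile chisq.test
#' @importFrom utils head read.delim write.table
NULL

#' MolecularGraph: a 2D molecular graph parsed from SMILES
#'
#' Atoms carry categorical type and chirality; bonds carry categorical bond
#' type and bond direction. The graph is undirected at the message-passing
#' level: every bond induces messages in both directions. `canonicalKey` is
#' the canonical SMILES of the input and is the dictionary key used by the
#' knowledge store.
#'
#' @slot atoms data.frame with columns `type`, `chirality` (character).
#' @slot bonds data.frame with columns `u`, `v` (1-based atom indices),
#'   `type`, `direction` (character).
#' @slot sourceSmiles the SMILES string the graph was parsed from.
#' @slot canonicalKey canonical SMILES; deterministic for chemically
#'   identical inputs.
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(
    atoms = "data.frame",
    bonds = "data.frame",
    sourceSmiles = "character",
    canonicalKey = "character"
  )
)

setValidity("MolecularGraph", function(object) {
  msg <- character()
  a <- object@atoms
  b <- object@bonds
  if (!all(c("type", "chirality") %in% names(a)))
    msg <- c(msg, "atoms must have columns 'type' and 'chirality'")
  if (!all(c("u", "v", "type", "direction") %in% names(b)))
    msg <- c(msg, "bonds must have columns 'u','v','type','direction'")
  if (nrow(a) < 1L) msg <- c(msg, "graph must contain at least one atom")
  if (nrow(b) > 0L) {
    if (any(b$u < 1L | b$u > nrow(a) | b$v < 1L | b$v > nrow(a)))
      msg <- c(msg, "bond endpoints must be valid atom indices")
    if (any(b$u == b$v)) msg <- c(msg, "self-bonds (u == v) are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' ProteinSequence: an amino-acid sequence with identifier
#'
#' Residues are restricted to the 20 standard amino acids plus the explicit
#' unknown symbol `X`. The canonical key of a protein is the uppercased
#' residue string itself.
#'
#' @slot id sequence identifier (FASTA header token).
#' @slot residues uppercase residue string.
#' @exportClass ProteinSequence
setClass("ProteinSequence",
  representation(id = "character", residues = "character")
)

setValidity("ProteinSequence", function(object) {
  msg <- character()
  if (length(object@residues) != 1L || !nzchar(object@residues))
    msg <- c(msg, "residues must be a nonempty string")
  else {
    bad <- setdiff(strsplit(object@residues, "")[[1]], aminoAcidAlphabet())
    if (length(bad))
      msg <- c(msg, paste0("illegal residue characters: ",
                           paste(unique(bad), collapse = ",")))
  }
  if (length(msg)) msg else TRUE
})

#' KnowledgeBase: entity set plus typed triplets
#'
#' Entities are kept in first-appearance order; this order is load-bearing
#' because it defines the row order of the knowledge-graph embedding matrix.
#'
#' @slot entities character vector of entity ids (ordered, unique).
#' @slot triplets data.frame with columns `h`, `r`, `t` (character),
#'   deduplicated.
#' @exportClass KnowledgeBase
setClass("KnowledgeBase",
  representation(entities = "character", triplets = "data.frame")
)

setValidity("KnowledgeBase", function(object) {
  msg <- character()
  tr <- object@triplets
  if (!all(c("h", "r", "t") %in% names(tr)))
    msg <- c(msg, "triplets must have columns 'h','r','t'")
  else if (nrow(tr) > 0L &&
           !all(c(tr$h, tr$t) %in% object@entities))
    msg <- c(msg, "every triplet head/tail must be a known entity")
  if (anyDuplicated(object@entities))
    msg <- c(msg, "entities must be unique")
  if (length(msg)) msg else TRUE
})

#' TaskTable: labeled rows for one prediction task
#'
#' @slot task one of `"DTI"`, `"DP"`, `"DDI"`, `"PPI"`.
#' @slot left character vector of structure keys (drug canonical SMILES or
#'   protein sequence keys).
#' @slot right character vector of structure keys for pair tasks, or
#'   zero-length for DP.
#' @slot labels numeric matrix (rows x nLabels) of 0/1 with `NA` marking
#'   missing labels (allowed for multi-task DP tables only).
#' @slot nLabels number of label columns.
#' @exportClass TaskTable
setClass("TaskTable",
  representation(task = "character", left = "character",
                 right = "character", labels = "matrix",
                 nLabels = "integer")
)

setValidity("TaskTable", function(object) {
  msg <- character()
  if (!object@task %in% c("DTI", "DP", "DDI", "PPI"))
    msg <- c(msg, "task must be one of DTI, DP, DDI, PPI")
  n <- length(object@left)
  if (object@task != "DP" && length(object@right) != n)
    msg <- c(msg, "pair tasks need a right key per row")
  if (object@task == "DP" && length(object@right) != 0L)
    msg <- c(msg, "DP tables must not carry right keys")
  if (nrow(object@labels) != n)
    msg <- c(msg, "labels must have one row per task row")
  if (ncol(object@labels) != object@nLabels)
    msg <- c(msg, "label matrix width must equal nLabels")
  if (object@nLabels < 1L) msg <- c(msg, "nLabels must be >= 1")
  vals <- object@labels[!is.na(object@labels)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    msg <- c(msg, "labels must be 0/1 or NA")
  if (any(is.na(object@labels)) &&
      !(object@task == "DP" && object@nLabels > 1L))
    msg <- c(msg, "missing labels are allowed only for multi-task DP tables")
  if (length(msg)) msg else TRUE
})

#' KgEmbedding: knowledge-graph embedding matrix with provenance
#'
#' One dense row per knowledge-base entity, in knowledge-base entity order.
#' Produced offline by [kgEmbed()] (randomized truncated SVD of the
#' degree-normalized adjacency followed by spectral propagation) and kept
#' frozen during model training.
#'
#' @slot matrix numeric |E| x dKg matrix.
#' @slot entityIndex named integer vector mapping entity id -> row.
#' @slot provenance list of the parameters used (dKg, oversampling,
#'   propagation order/theta/mu, seed, excluded test pairs).
#' @exportClass KgEmbedding
setClass("KgEmbedding",
  representation(matrix = "matrix", entityIndex = "integer",
                 provenance = "list")
)

setValidity("KgEmbedding", function(object) {
  msg <- character()
  if (is.null(names(object@entityIndex)))
    msg <- c(msg, "entityIndex must be named by entity id")
  if (length(object@entityIndex) != nrow(object@matrix))
    msg <- c(msg, "entityIndex must map every matrix row")
  if (length(object@entityIndex) &&
      !identical(sort(unname(object@entityIndex)),
                 seq_len(nrow(object@matrix))))
    msg <- c(msg, "entityIndex must be a bijection onto matrix rows")
  if (any(!is.finite(object@matrix)))
    msg <- c(msg, "embedding entries must be finite")
  if (length(msg)) msg else TRUE
})

#' KnowledgeStore: structure-keyed dictionary of multimodal knowledge
#'
#' Biomolecular structures serve as keys (canonical SMILES for drugs, the
#' uppercased sequence for proteins); values are the entity's knowledge-graph
#' identity and its text description. Lookup is exact-match on the canonical
#' key.
#'
#' @slot drugIndex named character vector: canonical SMILES -> entity id.
#' @slot proteinIndex named character vector: sequence key -> entity id.
#' @slot kb the [KnowledgeBase-class].
#' @slot texts named character vector: entity id -> description text.
#' @exportClass KnowledgeStore
setClass("KnowledgeStore",
  representation(drugIndex = "character", proteinIndex = "character",
                 kb = "KnowledgeBase", texts = "character")
)

setValidity("KnowledgeStore", function(object) {
  msg <- character()
  ids <- c(unname(object@drugIndex), unname(object@proteinIndex))
  if (length(ids) && !all(ids %in% object@kb@entities))
    msg <- c(msg, "every indexed entity id must exist in the knowledge base")
  if (length(object@texts) && is.null(names(object@texts)))
    msg <- c(msg, "texts must be named by entity id")
  if (length(msg)) msg else TRUE
})

#' SplitSpec: fold assignments with strategy-specific disjointness
#'
#' Constructed by [makeInteractionSplit()], [scaffoldSplit()] or
#' [ppiGraphSplit()]; the validity method re-checks the strategy's
#' disjointness guarantee so a violating split can never be instantiated.
#'
#' @slot strategy split strategy name.
#' @slot folds list of lists with integer row ids `train`, `valid`, `test`.
#' @slot seed integer seed the split was drawn with.
#' @slot provenance list (ratios, fold counts, entity groups, achieved
#'   ratios, and the per-row entity keys needed to audit disjointness).
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(strategy = "character", folds = "list",
                 seed = "integer", provenance = "list")
)

setValidity("SplitSpec", function(object) validateSplitSpec(object))

#' SyntheticCorpus: a toy multimodal corpus with planted signal
#'
#' Generated by [generateCorpus()]. Drugs and proteins belong to planted
#' communities mirrored in the knowledge graph (stochastic block model), in
#' their structures (community-specific SMILES backbones and sequence
#' motifs) and in their templated texts; a second, community-independent
#' structural bit ("motif id") is planted so that default task labels need
#' both the knowledge-graph and the structure channel.
#'
#' @slot store the [KnowledgeStore-class] (with a fraction `fMiss` of
#'   entities withheld from the indices to emulate missing modalities).
#' @slot drugs named list of [MolecularGraph-class], named by entity id.
#' @slot proteins named list of [ProteinSequence-class], named by entity id.
#' @slot groundTruth data.frame: entity_id, kind, community, motif, key.
#' @slot params list of generator parameters (and the seed).
#' @exportClass SyntheticCorpus
setClass("SyntheticCorpus",
  representation(store = "KnowledgeStore", drugs = "list",
                 proteins = "list", groundTruth = "data.frame",
                 params = "list")
)

#' MultimodalRecord: one biomolecule's resolved three-modality bundle
#'
#' @slot kind `"drug"` or `"protein"`.
#' @slot key canonical structure key.
#' @slot entityId resolved entity id, or NA on a store miss.
#' @slot zSK numeric structured-knowledge feature vector.
#' @slot skProvenance one of `"direct"`, `"reconstructed"`,
#'   `"masked_reconstructed"`.
#' @slot text description text ("" when absent).
#' @slot textPresent logical.
#' @exportClass MultimodalRecord
setClass("MultimodalRecord",
  representation(kind = "character", key = "character",
                 entityId = "character", zSK = "numeric",
                 skProvenance = "character", text = "character",
                 textPresent = "logical")
)

setValidity("MultimodalRecord", function(object) {
  ok <- object@skProvenance %in%
    c("direct", "reconstructed", "masked_reconstructed")
  if (!ok) return("skProvenance flag must always be set to a known value")
  TRUE
})
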