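## Multimodal knowledge acquisition: exact-match dictionary lookup in a
## structure-keyed store, top-k multi-head sparse-attention reconstruction
## of structured-knowledge features for store misses, and random modality
## masking during training (which forces and trains the reconstruction
## path).

#' Construct a KnowledgeStore
#'
#' @param kb a [KnowledgeBase-class].
#' @param drugIndex named character vector: canonical SMILES -> entity id.
#' @param proteinIndex named character vector: sequence key -> entity id.
#' @param texts named character vector: entity id -> description.
#' @return a [KnowledgeStore-class].
#' @export
knowledgeStore <- function(kb, drugIndex = character(),
                           proteinIndex = character(),
                           texts = character()) {
  new("KnowledgeStore", drugIndex = drugIndex,
      proteinIndex = proteinIndex, kb = kb, texts = texts)
}

#' Exact-match lookup of a structure key in the store
#'
#' Keys must already be canonical (canonical SMILES for drugs, uppercased
#' sequence for proteins), so chemically identical spellings resolve to the
#' same entity. A miss is a typed signal, not an error.
#'
#' @param store a [KnowledgeStore-class].
#' @param key canonical structure key.
#' @param kind `"drug"` or `"protein"`.
#' @return entity id, or a `"storeMiss"` object (test with [isStoreMiss()]).
#' @export
storeLookup <- function(store, key, kind = c("drug", "protein")) {
  kind <- match.arg(kind)
  idx <- if (kind == "drug") store@drugIndex else store@proteinIndex
  hit <- idx[key]
  if (is.na(hit)) return(structure(list(key = key, kind = kind),
                                   class = "storeMiss"))
  unname(hit)
}

#' Test for a store miss
#'
#' @param x result of [storeLookup()].
#' @return logical.
#' @export
isStoreMiss <- function(x) inherits(x, "storeMiss")

#' Write a knowledge store to a directory
#'
#' Layout: `kb.tsv` (triplets), `drugs.tsv` (canonical_smiles, entity_id),
#' `proteins.tsv` (sequence, entity_id), `texts.jsonl`, and
#' `entities.txt` preserving entity order.
#'
#' @param store a [KnowledgeStore-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeKnowledgeStore <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeKnowledgeBase(store@kb, file.path(dir, "kb.tsv"))
  writeLines(entities(store@kb), file.path(dir, "entities.txt"))
  writeLines(c("canonical_smiles\tentity_id",
               paste(names(store@drugIndex), store@drugIndex, sep = "\t")),
             file.path(dir, "drugs.tsv"))
  writeLines(c("sequence\tentity_id",
               paste(names(store@proteinIndex), store@proteinIndex,
                     sep = "\t")),
             file.path(dir, "proteins.tsv"))
  writeTextRecords(store@texts, file.path(dir, "texts.jsonl"))
  invisible(dir)
}

#' Read a knowledge store written by [writeKnowledgeStore()]
#'
#' @param dir directory path.
#' @return a [KnowledgeStore-class].
#' @export
readKnowledgeStore <- function(dir) {
  kb <- loadKnowledgeBase(file.path(dir, "kb.tsv"))
  entFile <- file.path(dir, "entities.txt")
  if (file.exists(entFile)) {
    tr <- triplets(kb)
    kb <- knowledgeBase(tr$h, tr$r, tr$t,
                        entities = readLines(entFile, warn = FALSE))
  }
  readIdx <- function(f) {
    df <- utils::read.delim(f, stringsAsFactors = FALSE,
                            check.names = FALSE)
    structure(as.character(df[[2]]), names = as.character(df[[1]]))
  }
  texts <- readTextRecords(file.path(dir, "texts.jsonl"))
  knowledgeStore(kb,
                 drugIndex = readIdx(file.path(dir, "drugs.tsv")),
                 proteinIndex = readIdx(file.path(dir, "proteins.tsv")),
                 texts = structure(texts$text, names = texts$entity_id))
}

#' Parameters of the top-k sparse-attention reconstruction module
#'
#' The value projection is fixed to the identity and is not a trainable
#' parameter -- reconstructed features are convex combinations of raw
#' knowledge-graph embedding rows, so the module is a trainable
#' interpolation over the k most query-similar entities.
#'
#' @param dStruct width of the incoming structure feature (query source).
#' @param dKg knowledge-graph embedding width; must be divisible by
#'   `nHeads`.
#' @param nHeads number of attention heads (default 4).
#' @param k number of entities kept per head (default 16).
#' @param seed seed for initialization.
#' @param init `"glorot"` or `"zero"` (zero keeps the structure projection
#'   useful in tests; W_Q/W_K start at identity-free glorot otherwise).
#' @return named list: `proj_W`, `proj_b`, `W_Q`, `W_K` and a `config`
#'   element.
#' @export
sparseAttentionParams <- function(dStruct, dKg, nHeads = 4L, k = 16L,
                                  seed = 1L, init = c("glorot", "zero")) {
  init <- match.arg(init)
  if (k < 1L) stop("k must be >= 1")
  if (dKg %% nHeads != 0L)
    stop("dKg (", dKg, ") must be divisible by nHeads (", nHeads, ")")
  set.seed(seed)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else glorot(nr, nc)
  }
  list(proj_W = mk(dStruct, dKg), proj_b = zerosVec(dKg),
       W_Q = mk(dKg, dKg), W_K = mk(dKg, dKg),
       config = list(dStruct = dStruct, dKg = dKg, nHeads = nHeads, k = k))
}

#' Reconstruct a structured-knowledge feature by top-k sparse attention
#'
#' The structure feature is projected into knowledge-graph space and used
#' as the query; keys are `W_K H` where `H` is the (frozen) embedding
#' matrix; values are the unprojected rows of `H`. Per head, scores are
#' scaled by `sqrt(dHead)`, only the `k` largest survive (ties at the k-th
#' score keep the lowest entity row index), the kept scores are
#' softmax-normalized and the head output is their convex combination of
#' selected `H` rows; head outputs are concatenated.
#'
#' @param zStruct numeric structure feature vector (length `dStruct`).
#' @param kgEmb a [KgEmbedding-class] (or plain |E| x dKg matrix).
#' @param params parameters from [sparseAttentionParams()].
#' @return numeric vector of length `dKg`; attribute `"attention"` holds
#'   the per-head selected indices and weights.
#' @export
sparseAttentionReconstruct <- function(zStruct, kgEmb, params) {
  fw <- sparseAttentionForward(zStruct, kgEmb, params)
  structure(fw$z, attention = fw$attention)
}

sparseAttentionForward <- function(zStruct, kgEmb, params) {
  H <- if (is(kgEmb, "KgEmbedding")) embeddingMatrix(kgEmb) else kgEmb
  if (is.null(dim(H)) || nrow(H) == 0L)
    stop("knowledge-graph embedding must have at least one row")
  cfg <- params$config
  if (cfg$k < 1L) stop("k must be >= 1")
  if (length(zStruct) != nrow(params$proj_W))
    stop("structure feature width ", length(zStruct),
         " does not match projection input ", nrow(params$proj_W))
  zp <- drop(denseForward(matrix(zStruct, nrow = 1L), params$proj_W,
                          params$proj_b))
  q <- drop(params$W_Q %*% zp)                  # length dKg
  K <- H %*% t(params$W_K)                      # |E| x dKg
  nE <- nrow(H)
  dHead <- cfg$dKg %/% cfg$nHeads
  kUse <- min(cfg$k, nE)
  z <- numeric(cfg$dKg)
  heads <- vector("list", cfg$nHeads)
  for (h in seq_len(cfg$nHeads)) {
    cols <- ((h - 1L) * dHead + 1L):(h * dHead)
    qh <- q[cols]
    scores <- drop(K[, cols, drop = FALSE] %*% qh) / sqrt(dHead)
    sel <- order(-scores, seq_len(nE))[seq_len(kUse)]  # ties: lowest index
    w <- softmaxVec(scores[sel])
    z[cols] <- drop(crossprod(H[sel, cols, drop = FALSE], w))
    heads[[h]] <- list(sel = sel, w = w, scores = scores, cols = cols)
  }
  list(z = z, attention = heads, zp = zp, q = q, K = K, H = H,
       dHead = dHead, zStruct = as.numeric(zStruct))
}

## Batched sparse attention over a matrix of structure features (one row
## per biomolecule needing reconstruction). The key matrix K = H W_K^T is
## computed once per call; top-k selection and the convex combination run
## per row per head on k-length vectors.
saBatchForward <- function(Zstruct, H, params) {
  cfg <- params$config
  nR <- nrow(Zstruct)
  nE <- nrow(H)
  dHead <- cfg$dKg %/% cfg$nHeads
  kUse <- min(cfg$k, nE)
  Zp <- denseForward(Zstruct, params$proj_W, params$proj_b)  # nR x dKg
  Q <- tcrossprod(Zp, params$W_Q)                            # rows q^T
  K <- tcrossprod(H, params$W_K)                             # nE x dKg
  Z <- matrix(0, nR, cfg$dKg)
  sel <- array(0L, c(nR, cfg$nHeads, kUse))
  w <- array(0, c(nR, cfg$nHeads, kUse))
  for (h in seq_len(cfg$nHeads)) {
    cols <- ((h - 1L) * dHead + 1L):(h * dHead)
    S <- tcrossprod(Q[, cols, drop = FALSE],
                    K[, cols, drop = FALSE]) / sqrt(dHead)   # nR x nE
    for (r in seq_len(nR)) {
      s <- S[r, ]
      ids <- order(-s, seq_len(nE))[seq_len(kUse)]
      ws <- softmaxVec(s[ids])
      sel[r, h, ] <- ids
      w[r, h, ] <- ws
      Z[r, cols] <- drop(crossprod(H[ids, cols, drop = FALSE], ws))
    }
  }
  list(Z = Z, sel = sel, w = w, Zp = Zp, Q = Q, K = K, H = H,
       dHead = dHead, Zstruct = Zstruct, kUse = kUse)
}

saBatchBackward <- function(dZ, fw, params) {
  cfg <- params$config
  nR <- nrow(dZ)
  dHead <- fw$dHead
  dQ <- matrix(0, nR, cfg$dKg)
  dK <- matrix(0, nrow(fw$H), cfg$dKg)
  for (h in seq_len(cfg$nHeads)) {
    cols <- ((h - 1L) * dHead + 1L):(h * dHead)
    for (r in seq_len(nR)) {
      ids <- fw$sel[r, h, ]
      ws <- fw$w[r, h, ]
      Hsel <- fw$H[ids, cols, drop = FALSE]
      dw <- drop(Hsel %*% dZ[r, cols])
      dscore <- softmaxBackward(ws, dw) / sqrt(dHead)
      dQ[r, cols] <- drop(crossprod(fw$K[ids, cols, drop = FALSE],
                                    dscore))
      dK[ids, cols] <- dK[ids, cols, drop = FALSE] +
        tcrossprod(dscore, fw$Q[r, cols])
    }
  }
  dZp <- dQ %*% params$W_Q
  gW_Q <- crossprod(dQ, fw$Zp)
  gW_K <- crossprod(dK, fw$H)
  gproj_W <- crossprod(fw$Zstruct, dZp)
  dZstruct <- tcrossprod(dZp, params$proj_W)
  list(grads = list(W_Q = gW_Q, W_K = gW_K, proj_W = gproj_W,
                    proj_b = colSums(dZp)),
       dZstruct = dZstruct)
}

sparseAttentionBackward <- function(dz, fw, params) {
  cfg <- params$config
  dq <- numeric(cfg$dKg)
  dK <- matrix(0, nrow(fw$H), cfg$dKg)
  for (h in seq_along(fw$attention)) {
    at <- fw$attention[[h]]
    cols <- at$cols
    Hsel <- fw$H[at$sel, cols, drop = FALSE]
    dw <- drop(Hsel %*% dz[cols])               # dL/dw_i
    dscore <- softmaxBackward(at$w, dw) / sqrt(fw$dHead)
    ## scores_i = K[sel_i, cols] . q[cols]
    dq[cols] <- drop(crossprod(fw$K[at$sel, cols, drop = FALSE], dscore))
    dK[at$sel, cols] <- dK[at$sel, cols, drop = FALSE] +
      tcrossprod(dscore, fw$q[cols])
  }
  ## q = W_Q zp ; K = H W_K^T ; zp = zStruct proj_W + proj_b.
  ## W_V = I is frozen by construction: it is not a parameter at all, so
  ## no training step can ever move it.
  dW_Q <- tcrossprod(dq, fw$zp)
  dzp <- drop(crossprod(params$W_Q, dq))
  dW_K <- crossprod(dK, fw$H)
  dproj_W <- tcrossprod(fw$zStruct, dzp)
  dzStruct <- drop(tcrossprod(matrix(dzp, nrow = 1L), params$proj_W))
  list(grads = list(W_Q = dW_Q, W_K = dW_K, proj_W = dproj_W,
                    proj_b = dzp),
       dzStruct = dzStruct)
}

#' Randomly mask a direct structured-knowledge feature
#'
#' With probability `P` the record's direct feature is discarded and the
#' record is flagged so that resolution uses sparse-attention
#' reconstruction; the draw is independent per record per epoch. Masking a
#' record that is not `direct` is a no-op. `P = 0` never masks (the
#' evaluation setting); `P = 1` always masks.
#'
#' @param record a [MultimodalRecord-class].
#' @param P masking probability in `[0, 1]`.
#' @return the (possibly flagged) record.
#' @export
applyModalityMasking <- function(record, P) {
  if (!is.numeric(P) || P < 0 || P > 1)
    stop("masking probability P must be in [0, 1]")
  if (record@skProvenance != "direct") return(record)
  if (P > 0 && runif(1) < P) {
    record@zSK <- numeric()
    record@skProvenance <- "masked_reconstructed"
  }
  record
}

#' Resolve a biomolecule's three modalities
#'
#' Store hit and not masked: the structured feature is the entity's direct
#' embedding row (provenance `"direct"`) and the text is the stored
#' description. Store miss, or masked during training: the structured
#' feature is reconstructed with sparse attention from the structure
#' feature (provenance `"reconstructed"` / `"masked_reconstructed"`); on a
#' miss the text is absent and is encoded as the empty string.
#'
#' @param store a [KnowledgeStore-class].
#' @param kgEmb a [KgEmbedding-class].
#' @param saParams parameters from [sparseAttentionParams()].
#' @param key canonical structure key of the biomolecule.
#' @param kind `"drug"` or `"protein"`.
#' @param zStruct structure feature vector (already encoded).
#' @param training logical; masking is applied only when training.
#' @param P masking probability (use 0 at evaluation).
#' @return a [MultimodalRecord-class].
#' @export
resolveRecord <- function(store, kgEmb, saParams, key, kind, zStruct,
                          training = FALSE, P = 0) {
  hit <- storeLookup(store, key, kind)
  if (!isStoreMiss(hit)) {
    row <- lookupEmbedding(kgEmb, hit)
    if (!isKgMiss(row)) {
      txt <- store@texts[hit]
      rec <- new("MultimodalRecord", kind = kind, key = key,
                 entityId = hit, zSK = row, skProvenance = "direct",
                 text = ifelse(is.na(txt), "", unname(txt)),
                 textPresent = !is.na(txt))
      if (training && P > 0) rec <- applyModalityMasking(rec, P)
      if (rec@skProvenance == "masked_reconstructed")
        rec@zSK <- as.numeric(sparseAttentionReconstruct(zStruct, kgEmb,
                                                         saParams))
      return(rec)
    }
  }
  zsk <- as.numeric(sparseAttentionReconstruct(zStruct, kgEmb, saParams))
  new("MultimodalRecord", kind = kind, key = key,
      entityId = NA_character_, zSK = zsk,
      skProvenance = "reconstructed", text = "", textPresent = FALSE)
}
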