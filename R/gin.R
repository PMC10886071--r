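## Graph isomorphism network (GIN) encoder for molecular graphs.
##
## Node features are initialized from atom-type and chirality embedding
## tables; each layer updates node v as
##   x_v <- MLP^(k)( x_v + sum_{u in N(v)} ( x_u + e_{(u,v)}^k ) )
## where e is the layer's bond-type + bond-direction embedding of the bond
## joining u and v, and messages flow along both directions of every bond.
## The whole-graph feature is the mean over node rows of the last layer.
##
## Edge embeddings live at the layer's input width so the sum typechecks;
## the raw bond featurization is the (type, direction) categorical pair.

#' Parameters of the GIN drug structure encoder
#'
#' Embedding tables cover the full categorical vocabulary plus the unknown
#' bucket. Each layer's MLP is a fully connected layer, a ReLU, and another
#' fully connected layer (inner width `2 * dout`).
#'
#' @param nLayers number of GIN layers (default 5).
#' @param nodeEmbedDim width of the initial atom embedding (default 120).
#' @param hiddenDim width of every layer output and of the whole-graph
#'   feature. Configurable: 300 emulates the pretrained encoder's scale,
#'   smaller values are used at desk scale.
#' @param seed seed for weight initialization.
#' @param init `"glorot"` or `"zero"` (zero tables are useful in tests).
#' @param layerNorm apply a trainable per-node layer normalization after
#'   every layer (default `FALSE`). Normalization keeps node-feature
#'   scales bounded over deep message passing during end-to-end training;
#'   it is deterministic at evaluation (no batch statistics).
#' @return named list of parameter arrays plus a `config` element.
#' @export
ginParams <- function(nLayers = 5L, nodeEmbedDim = 120L, hiddenDim = 64L,
                      seed = 1L, init = c("glorot", "zero"),
                      layerNorm = FALSE) {
  init <- match.arg(init)
  stopifnot(nLayers >= 1L)
  vocab <- moleculeVocab()
  set.seed(seed)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else glorot(nr, nc)
  }
  p <- list(
    atom_embed = mk(length(vocab$atomTypes), nodeEmbedDim),
    chir_embed = mk(length(vocab$chirality), nodeEmbedDim)
  )
  din <- nodeEmbedDim
  for (k in seq_len(nLayers)) {
    p[[paste0("bond_embed_", k)]] <- mk(length(vocab$bondTypes), din)
    p[[paste0("dir_embed_", k)]] <- mk(length(vocab$bondDirections), din)
    p[[paste0("mlp_W1_", k)]] <- mk(din, 2L * hiddenDim)
    p[[paste0("mlp_b1_", k)]] <- zerosVec(2L * hiddenDim)
    p[[paste0("mlp_W2_", k)]] <- mk(2L * hiddenDim, hiddenDim)
    p[[paste0("mlp_b2_", k)]] <- zerosVec(hiddenDim)
    if (layerNorm) {
      p[[paste0("ln_gamma_", k)]] <- rep(1, hiddenDim)
      p[[paste0("ln_beta_", k)]] <- zerosVec(hiddenDim)
    }
    din <- hiddenDim
  }
  p$config <- list(nLayers = nLayers, nodeEmbedDim = nodeEmbedDim,
                   hiddenDim = hiddenDim, layerNorm = layerNorm)
  p
}

## Categorical indices of a graph against the package vocabularies.
ginGraphIndices <- function(graph) {
  vocab <- moleculeVocab()
  a <- atoms(graph)
  b <- bonds(graph)
  list(
    atomIdx = match(a$type, vocab$atomTypes,
                    nomatch = length(vocab$atomTypes)),
    chirIdx = match(a$chirality, vocab$chirality,
                    nomatch = length(vocab$chirality)),
    u = b$u, v = b$v,
    bondIdx = match(b$type, vocab$bondTypes,
                    nomatch = length(vocab$bondTypes)),
    dirIdx = match(b$direction, vocab$bondDirections,
                   nomatch = length(vocab$bondDirections)),
    nAtoms = nrow(a)
  )
}

#' Initial node feature matrix of a molecular graph
#'
#' Row v is the atom-type embedding plus the chirality embedding of atom v.
#'
#' @param graph a [MolecularGraph-class].
#' @param params parameters from [ginParams()].
#' @return numeric |V| x nodeEmbedDim matrix.
#' @export
initNodeFeatures <- function(graph, params) {
  ix <- ginGraphIndices(graph)
  params$atom_embed[ix$atomIdx, , drop = FALSE] +
    params$chir_embed[ix$chirIdx, , drop = FALSE]
}

#' One GIN message-passing layer
#'
#' @param nodeFeats |V| x din matrix of node features.
#' @param graph a [MolecularGraph-class].
#' @param layerIndex 1-based layer number (selects the layer's edge
#'   embedding tables and MLP).
#' @param params parameters from [ginParams()].
#' @return updated |V| x hiddenDim node feature matrix.
#' @export
ginLayer <- function(nodeFeats, graph, layerIndex, params) {
  fw <- ginLayerForward(nodeFeats, ginGraphIndices(graph), layerIndex,
                        params)
  fw$H
}

## Sparse symmetric adjacency of the (batched) graph; neighbor sums are
## then single sparse-dense products.
ginAdjacency <- function(ix) {
  if (!length(ix$u))
    return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                x = numeric(),
                                dims = c(ix$nAtoms, ix$nAtoms)))
  Matrix::sparseMatrix(i = c(ix$u, ix$v), j = c(ix$v, ix$u), x = 1,
                       dims = c(ix$nAtoms, ix$nAtoms))
}

## Forward with cache. Aggregation: for each bond (u,v) the message
## x_u + e goes to v and x_v + e goes to u, i.e.
##   M = X + A X + edgeSum,  edgeSum_v = sum of incident bond embeddings.
ginLayerForward <- function(X, ix, k, params) {
  W1 <- params[[paste0("mlp_W1_", k)]]
  if (ncol(X) != nrow(W1))
    stop("gin layer ", k, ": node feature width ", ncol(X),
         " does not match layer input width ", nrow(W1))
  if (is.null(ix$A)) ix$A <- ginAdjacency(ix)
  M <- X
  if (length(ix$u)) {
    E <- params[[paste0("bond_embed_", k)]][ix$bondIdx, , drop = FALSE] +
      params[[paste0("dir_embed_", k)]][ix$dirIdx, , drop = FALSE]
    M <- M + as.matrix(ix$A %*% X) +
      rowsumInto(E, ix$v, ix$nAtoms) + rowsumInto(E, ix$u, ix$nAtoms)
  }
  A1 <- denseForward(M, W1, params[[paste0("mlp_b1_", k)]])
  pos <- A1 > 0
  R1 <- A1 * pos
  H <- denseForward(R1, params[[paste0("mlp_W2_", k)]],
                    params[[paste0("mlp_b2_", k)]])
  ln <- NULL
  if (isTRUE(params$config$layerNorm)) {
    ln <- layerNormForward(H, params[[paste0("ln_gamma_", k)]],
                           params[[paste0("ln_beta_", k)]])
    H <- ln$Y
  }
  list(H = H, M = M, pos = pos, R1 = R1, A1 = A1, X = X, A = ix$A,
       ln = ln)
}

ginLayerBackward <- function(dH, cache, ix, k, params) {
  g <- list()
  if (!is.null(cache$ln)) {
    bln <- layerNormBackward(dH, cache$ln,
                             params[[paste0("ln_gamma_", k)]])
    g[[paste0("ln_gamma_", k)]] <- bln$dgamma
    g[[paste0("ln_beta_", k)]] <- bln$dbeta
    dH <- bln$dX
  }
  b2 <- denseBackward(cache$R1, params[[paste0("mlp_W2_", k)]], dH)
  g[[paste0("mlp_W2_", k)]] <- b2$dW
  g[[paste0("mlp_b2_", k)]] <- b2$db
  dA1 <- b2$dX * cache$pos
  b1 <- denseBackward(cache$M, params[[paste0("mlp_W1_", k)]], dA1)
  g[[paste0("mlp_W1_", k)]] <- b1$dW
  g[[paste0("mlp_b1_", k)]] <- b1$db
  dM <- b1$dX
  dX <- dM
  if (length(ix$u)) {
    dX <- dX + as.matrix(cache$A %*% dM)   # A is symmetric
    dE <- dM[ix$v, , drop = FALSE] + dM[ix$u, , drop = FALSE]
    vocab <- moleculeVocab()
    g[[paste0("bond_embed_", k)]] <-
      rowsumInto(dE, ix$bondIdx, length(vocab$bondTypes))
    g[[paste0("dir_embed_", k)]] <-
      rowsumInto(dE, ix$dirIdx, length(vocab$bondDirections))
  }
  list(grads = g, dX = dX)
}

## rowsum with a fixed number of output rows (zero rows kept).
rowsumInto <- function(X, group, n) {
  out <- matrix(0, n, ncol(X))
  agg <- rowsum(X, group = group)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

## Combine per-graph index bundles into one block-diagonal batch: the
## message-passing algebra is identical on the disjoint union, so a batch
## of molecules runs through the layers in single matrix operations.
ginCombineIndices <- function(ixList) {
  sizes <- vapply(ixList, `[[`, 0L, "nAtoms")
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  list(
    atomIdx = unlist(lapply(ixList, `[[`, "atomIdx")),
    chirIdx = unlist(lapply(ixList, `[[`, "chirIdx")),
    u = unlist(mapply(function(ix, o) ix$u + o, ixList, offsets,
                      SIMPLIFY = FALSE)),
    v = unlist(mapply(function(ix, o) ix$v + o, ixList, offsets,
                      SIMPLIFY = FALSE)),
    bondIdx = unlist(lapply(ixList, `[[`, "bondIdx")),
    dirIdx = unlist(lapply(ixList, `[[`, "dirIdx")),
    nAtoms = sum(sizes),
    graphOf = rep(seq_along(sizes), sizes),
    sizes = sizes
  )
}

#' Encode a drug molecular graph into a fixed-length structure feature
#'
#' Runs [initNodeFeatures()] and `nLayers` GIN layers, then mean-pools the
#' last layer's node features. Invariant to any permutation of atom
#' indices.
#'
#' @param graph a [MolecularGraph-class].
#' @param params parameters from [ginParams()].
#' @return numeric vector of length `hiddenDim`.
#' @export
encodeDrug <- function(graph, params) {
  encodeDrugForward(graph, params)$z
}

encodeDrugForward <- function(graph, params) {
  fw <- encodeDrugsForward(list(ginGraphIndices(graph)), params)
  fw$z <- fw$Z[1, ]
  fw
}

encodeDrugBackward <- function(dz, fw, params) {
  encodeDrugsBackward(matrix(dz, nrow = 1L), fw, params)
}

## Batched forward over a list of graph index bundles.
encodeDrugsForward <- function(ixList, params) {
  ix <- ginCombineIndices(ixList)
  if (ix$nAtoms < 1L) stop("cannot encode an empty molecular graph")
  ix$A <- ginAdjacency(ix)
  X <- params$atom_embed[ix$atomIdx, , drop = FALSE] +
    params$chir_embed[ix$chirIdx, , drop = FALSE]
  caches <- vector("list", params$config$nLayers)
  for (k in seq_len(params$config$nLayers)) {
    caches[[k]] <- ginLayerForward(X, ix, k, params)
    X <- caches[[k]]$H
  }
  Z <- rowsum(X, ix$graphOf) / ix$sizes
  list(Z = Z, caches = caches, ix = ix)
}

## dZ: nGraphs x hidden matrix of upstream gradients.
encodeDrugsBackward <- function(dZ, fw, params) {
  ix <- fw$ix
  grads <- list()
  dX <- (dZ / ix$sizes)[ix$graphOf, , drop = FALSE]
  for (k in rev(seq_len(params$config$nLayers))) {
    bk <- ginLayerBackward(dX, fw$caches[[k]], ix, k, params)
    grads <- accumulateGrads(grads, bk$grads)
    dX <- bk$dX
  }
  vocab <- moleculeVocab()
  grads$atom_embed <- rowsumInto(dX, ix$atomIdx, length(vocab$atomTypes))
  grads$chir_embed <- rowsumInto(dX, ix$chirIdx, length(vocab$chirality))
  grads
}
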