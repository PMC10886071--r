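## Knowledge-graph embedding: randomized truncated SVD of the
## degree-normalized adjacency followed by a Chebyshev band-pass spectral
## propagation, with leakage-aware removal of test-pair edges. The result
## is a dense |E| x dKg matrix, frozen during model training; structured
## knowledge features are row lookups into it.

#' Remove knowledge-base triplets matching declared test pairs
#'
#' Every triplet whose unordered endpoint pair `{h, t}` equals a test pair
#' is dropped, regardless of relation type; the entity set is unchanged.
#' Pairs absent from the knowledge base are ignored. This is the leakage
#' guard run before computing embeddings for any evaluation.
#'
#' @param kb a [KnowledgeBase-class].
#' @param testPairs a two-column matrix/data.frame of entity ids, or a
#'   list of length-2 character vectors; pairs are unordered.
#' @return a new [KnowledgeBase-class].
#' @export
removeTestLinks <- function(kb, testPairs) {
  tr <- triplets(kb)
  if (is.data.frame(testPairs)) testPairs <- as.matrix(testPairs)
  if (is.list(testPairs) && !is.matrix(testPairs))
    testPairs <- do.call(rbind, testPairs)
  if (is.null(testPairs) || length(testPairs) == 0L ||
      nrow(testPairs) == 0L)
    return(knowledgeBase(tr$h, tr$r, tr$t, entities = entities(kb)))
  pairKey <- function(a, b)
    paste(pmin(as.character(a), as.character(b)),
          pmax(as.character(a), as.character(b)), sep = "\r")
  banned <- unique(pairKey(testPairs[, 1], testPairs[, 2]))
  keep <- !(pairKey(tr$h, tr$t) %in% banned)
  knowledgeBase(tr$h[keep], tr$r[keep], tr$t[keep],
                entities = entities(kb))
}

#' Unweighted undirected adjacency of a knowledge base
#'
#' Relation labels and triplet direction are discarded; parallel triplets
#' between the same pair collapse to a single edge and self-loops are
#' dropped. Rows/columns follow knowledge-base entity order.
#'
#' @param kb a [KnowledgeBase-class].
#' @return a sparse symmetric `Matrix::sparseMatrix` over |E| nodes.
#' @export
buildAdjacency <- function(kb) {
  ents <- entities(kb)
  if (!length(ents)) stop("knowledge base has no entities")
  tr <- triplets(kb)
  n <- length(ents)
  if (!nrow(tr)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                x = numeric(), dims = c(n, n),
                                dimnames = list(ents, ents)))
  }
  i <- match(tr$h, ents)
  j <- match(tr$t, ents)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), dimnames = list(ents, ents))
  A@x[] <- 1  # collapse parallel edges
  A
}

## Row-normalized adjacency D^{-1} A with zero rows for isolated nodes.
rowNormalize <- function(A) {
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(x = inv) %*% A
}

#' Randomized truncated SVD embedding of the normalized adjacency
#'
#' Computes the leading `dKg` singular triplets of the row-normalized
#' adjacency (rows scaled by inverse degree; isolated nodes give zero
#' rows) by the randomized range-finder algorithm with two power
#' iterations, and returns `U * sqrt(S)`. Deterministic for a fixed seed;
#' singular-vector signs are fixed so the largest-magnitude entry of each
#' left vector is positive. The dense factors are attached as attributes
#' `u`, `d`, `v` so the low-rank reconstruction can be audited.
#'
#' @param adjacency sparse adjacency from [buildAdjacency()].
#' @param dKg embedding dimension (default 256); must be <= |E|.
#' @param oversampling extra random probe columns (default 10).
#' @param seed RNG seed.
#' @param nPower number of power iterations (default 2).
#' @return |E| x dKg numeric matrix with factor attributes.
#' @export
tsvdEmbed <- function(adjacency, dKg = 256L, oversampling = 10L,
                      seed = 1L, nPower = 2L) {
  n <- nrow(adjacency)
  if (dKg > n)
    stop("embedding dimension dKg = ", dKg,
         " exceeds the number of entities (", n, ")")
  An <- rowNormalize(adjacency)
  set.seed(deriveSeed(seed, "tsvd"))
  p <- min(n - dKg, oversampling)
  Omega <- matrix(rnorm(n * (dKg + p)), n, dKg + p)
  Y <- as.matrix(An %*% Omega)
  Q <- qr.Q(qr(Y))
  for (it in seq_len(nPower)) {
    Z <- as.matrix(Matrix::crossprod(An, Q))
    Qz <- qr.Q(qr(Z))
    Y <- as.matrix(An %*% Qz)
    Q <- qr.Q(qr(Y))
  }
  B <- as.matrix(Matrix::crossprod(Q, An))   # (dKg+p) x n
  sv <- svd(B)
  U <- Q %*% sv$u[, seq_len(dKg), drop = FALSE]
  V <- sv$v[, seq_len(dKg), drop = FALSE]
  d <- sv$d[seq_len(dKg)]
  for (jj in seq_len(dKg)) {      # deterministic sign convention
    imax <- which.max(abs(U[, jj]))
    if (U[imax, jj] < 0) { U[, jj] <- -U[, jj]; V[, jj] <- -V[, jj] }
  }
  iso <- Matrix::rowSums(adjacency) == 0
  U[iso, ] <- 0
  emb <- U * rep(sqrt(pmax(d, 0)), each = n)
  attr(emb, "u") <- U
  attr(emb, "d") <- d
  attr(emb, "v") <- V
  emb
}

## Chebyshev band-pass coefficients: Bessel-weighted expansion of a
## Gaussian-modulated kernel evaluated at band center mu.
chebyshevCoefficients <- function(order, theta, mu) {
  k <- 0:order
  muc <- max(-1, min(1, mu))
  (2 - (k == 0)) * exp(-theta) * besselI(theta, k) * cos(k * acos(muc))
}

#' Spectral propagation of node embeddings
#'
#' Applies a degree-normalized Chebyshev polynomial band-pass filter of the
#' given order to the embedding matrix:
#' `H = sum_k c_k T_k(Ahat) X` with `Ahat = D^{-1/2} A D^{-1/2}` and
#' Bessel-weighted coefficients `c_k(theta, mu)` evaluated by the
#' three-term Chebyshev recurrence. Order 0 reduces to a scaling of the
#' input; by convention a graph with no edges also short-circuits to the
#' order-0 scaling (there is no structure to propagate).
#'
#' @param embeddings |E| x d matrix (e.g. from [tsvdEmbed()]).
#' @param adjacency sparse adjacency from [buildAdjacency()].
#' @param order polynomial order (default 10).
#' @param theta Gaussian sharpness of the kernel (default 0.5).
#' @param mu band center in normalized-spectrum coordinates (default 0.2).
#' @return matrix of the same shape, all entries finite.
#' @export
spectralPropagate <- function(embeddings, adjacency, order = 10L,
                              theta = 0.5, mu = 0.2) {
  if (order < 0L) stop("propagation order must be >= 0")
  if (nrow(embeddings) != nrow(adjacency))
    stop("embedding row count must equal the number of entities")
  cs <- chebyshevCoefficients(order, theta, mu)
  nEdges <- Matrix::nnzero(adjacency)
  if (order == 0L || nEdges == 0L) return(cs[1] * embeddings)
  deg <- Matrix::rowSums(adjacency)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Ahat <- Matrix::Diagonal(x = inv) %*% adjacency %*%
    Matrix::Diagonal(x = inv)
  Tprev <- embeddings
  Tcur <- as.matrix(Ahat %*% embeddings)
  H <- cs[1] * Tprev + cs[2] * Tcur
  if (order >= 2L) {
    for (k in 2:order) {
      Tnext <- 2 * as.matrix(Ahat %*% Tcur) - Tprev
      H <- H + cs[k + 1] * Tnext
      Tprev <- Tcur
      Tcur <- Tnext
    }
  }
  H
}

#' Full knowledge-graph embedding pipeline
#'
#' Optionally removes declared test links, builds the adjacency, embeds it
#' with [tsvdEmbed()] and enhances with [spectralPropagate()]. Deterministic
#' given (knowledge base, parameters, seed).
#'
#' @param kb a [KnowledgeBase-class].
#' @param dKg embedding dimension (default 256).
#' @param testPairs optional unordered entity-id pairs to exclude before
#'   embedding (leakage guard).
#' @param oversampling,order,theta,mu,seed see [tsvdEmbed()] and
#'   [spectralPropagate()].
#' @return a [KgEmbedding-class] whose provenance records every parameter
#'   and the excluded pairs.
#' @export
kgEmbed <- function(kb, dKg = 256L, testPairs = NULL, oversampling = 10L,
                    order = 10L, theta = 0.5, mu = 0.2, seed = 1L) {
  kbUse <- if (!is.null(testPairs)) removeTestLinks(kb, testPairs) else kb
  A <- buildAdjacency(kbUse)
  emb <- tsvdEmbed(A, dKg = dKg, oversampling = oversampling, seed = seed)
  attr(emb, "u") <- NULL; attr(emb, "d") <- NULL; attr(emb, "v") <- NULL
  H <- spectralPropagate(emb, A, order = order, theta = theta, mu = mu)
  ents <- entities(kbUse)
  excluded <- if (is.null(testPairs)) list() else testPairs
  new("KgEmbedding",
      matrix = unname(as.matrix(H)),
      entityIndex = structure(seq_along(ents), names = ents),
      provenance = list(dKg = dKg, oversampling = oversampling,
                        order = order, theta = theta, mu = mu,
                        seed = seed, excludedPairs = excluded))
}

#' Look up an entity's structured-knowledge feature
#'
#' Returns the entity's embedding row, or a typed miss signal (`NULL` with
#' class `"kgMiss"`) when the entity is absent -- never a silent zero.
#'
#' @param kgEmb a [KgEmbedding-class].
#' @param entityId entity id.
#' @return numeric row vector, or a `"kgMiss"` object.
#' @export
lookupEmbedding <- function(kgEmb, entityId) {
  row <- kgEmb@entityIndex[entityId]
  if (is.na(row)) return(structure(list(entityId = entityId),
                                   class = "kgMiss"))
  kgEmb@matrix[row, ]
}

#' Test for a structured-knowledge lookup miss
#'
#' @param x result of [lookupEmbedding()].
#' @return logical.
#' @export
isKgMiss <- function(x) inherits(x, "kgMiss")

#' Export a knowledge-graph embedding to disk
#'
#' Writes the matrix as TSV (entity id + values) and a JSON provenance
#' sidecar recording the configuration, seed and excluded pairs.
#'
#' @param kgEmb a [KgEmbedding-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportKgEmbedding <- function(kgEmb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(sort(kgEmb@entityIndex))
  df <- data.frame(entity_id = ids,
                   kgEmb@matrix[kgEmb@entityIndex[ids], , drop = FALSE])
  utils::write.table(df, file.path(dir, "embedding.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(kgEmb@provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Import a knowledge-graph embedding written by [exportKgEmbedding()]
#'
#' @param dir directory path.
#' @return a [KgEmbedding-class].
#' @export
importKgEmbedding <- function(dir) {
  df <- utils::read.delim(file.path(dir, "embedding.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  prov <- jsonlite::fromJSON(file.path(dir, "provenance.json"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  new("KgEmbedding", matrix = mat,
      entityIndex = structure(seq_len(nrow(df)), names = df$entity_id),
      provenance = as.list(prov))
}
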