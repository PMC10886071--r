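## Shared fixtures and independent oracles for the test suite. Oracles are
## deliberately naive (per-node loops, dense algebra, explicit sorting) and
## never share code with the implementation paths they check.

## A random molecular graph built directly from the domain vocabularies
## (no SMILES round trip), for message-passing and permutation tests.
randomMolGraph <- function(nAtoms, nBonds = NULL) {
  vocab <- moleculeVocab()
  if (is.null(nBonds))
    nBonds <- if (nAtoms > 1L) sample(nAtoms - 1L, 1L) else 0L
  atoms <- data.frame(
    type = sample(head(vocab$atomTypes, 8), nAtoms, replace = TRUE),
    chirality = sample(vocab$chirality, nAtoms, replace = TRUE),
    stringsAsFactors = FALSE)
  bonds <- data.frame(u = integer(), v = integer(), type = character(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nBonds > 0L && nAtoms > 1L) {
    seen <- character()
    while (nrow(bonds) < nBonds) {
      uv <- sort(sample(nAtoms, 2L))
      key <- paste(uv, collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      bonds <- rbind(bonds, data.frame(
        u = uv[1], v = uv[2],
        type = sample(vocab$bondTypes, 1L),
        direction = sample(vocab$bondDirections, 1L),
        stringsAsFactors = FALSE))
    }
  }
  new("MolecularGraph", atoms = atoms, bonds = bonds,
      sourceSmiles = "<synthetic>", canonicalKey = "<synthetic>")
}

## Permute the atom order of a graph (bond endpoints remapped).
permuteMolGraph <- function(graph, perm) {
  a <- atoms(graph)[order(perm), , drop = FALSE]
  rownames(a) <- NULL
  b <- bonds(graph)
  b$u <- perm[b$u]
  b$v <- perm[b$v]
  new("MolecularGraph", atoms = a, bonds = b,
      sourceSmiles = graph@sourceSmiles, canonicalKey = graph@canonicalKey)
}

## Naive per-node message-passing oracle for one GIN layer: explicit
## neighbor enumeration, no adjacency algebra.
ginLayerOracle <- function(X, graph, k, params) {
  vocab <- moleculeVocab()
  a <- atoms(graph); b <- bonds(graph)
  W1 <- params[[paste0("mlp_W1_", k)]]; b1 <- params[[paste0("mlp_b1_", k)]]
  W2 <- params[[paste0("mlp_W2_", k)]]; b2 <- params[[paste0("mlp_b2_", k)]]
  BE <- params[[paste0("bond_embed_", k)]]
  DE <- params[[paste0("dir_embed_", k)]]
  out <- matrix(0, nrow(a), ncol(W2))
  for (v in seq_len(nrow(a))) {
    m <- X[v, ]
    if (nrow(b)) for (e in seq_len(nrow(b))) {
      other <- if (b$u[e] == v) b$v[e] else if (b$v[e] == v) b$u[e] else NA
      if (is.na(other)) next
      ebt <- match(b$type[e], vocab$bondTypes,
                   nomatch = length(vocab$bondTypes))
      ebd <- match(b$direction[e], vocab$bondDirections,
                   nomatch = length(vocab$bondDirections))
      m <- m + X[other, ] + BE[ebt, ] + DE[ebd, ]
    }
    h <- pmax(drop(m %*% W1) + b1, 0)
    out[v, ] <- drop(h %*% W2) + b2
  }
  out
}

## Explicit sliding-window convolution oracle for the protein encoder.
mcnnOracle <- function(seqStr, params) {
  alpha <- aminoAcidAlphabet()
  chars <- strsplit(toupper(seqStr), "")[[1]]
  idx <- match(chars, alpha, nomatch = match("X", alpha))
  while (length(idx) < 7L) idx <- c(idx, length(alpha) + 1L)
  E <- params$res_embed[idx, , drop = FALSE]
  ch <- params$config$channels
  convOne <- function(X, W, b) {
    nw <- nrow(X) - 2L
    out <- matrix(0, nw, ch)
    for (t in seq_len(nw)) {
      win <- c(X[t, ], X[t + 1L, ], X[t + 2L, ])
      out[t, ] <- pmax(drop(win %*% W) + b, 0)
    }
    out
  }
  pooled <- numeric(0)
  for (br in 1:3) {
    X <- E
    for (l in seq_len(br))
      X <- convOne(X, params[[sprintf("conv_W_%d_%d", br, l)]],
                   params[[sprintf("conv_b_%d_%d", br, l)]])
    pooled <- c(pooled, apply(X, 2, max))
  }
  drop(pooled %*% params$W_P) + params$b_P
}

## Oracle variant operating directly on an embedded residue matrix
## (bypasses the embedding lookup; used for linear-limit checks).
mcnnOracleEmbedded <- function(E, params, activation = function(x) pmax(x, 0)) {
  ch <- params$config$channels
  convOne <- function(X, W, b) {
    nw <- nrow(X) - 2L
    out <- matrix(0, nw, ch)
    for (t in seq_len(nw)) {
      win <- c(X[t, ], X[t + 1L, ], X[t + 2L, ])
      out[t, ] <- activation(drop(win %*% W) + b)
    }
    out
  }
  pooled <- numeric(0)
  for (br in 1:3) {
    X <- E
    for (l in seq_len(br))
      X <- convOne(X, params[[sprintf("conv_W_%d_%d", br, l)]],
                   params[[sprintf("conv_b_%d_%d", br, l)]])
    pooled <- c(pooled, apply(X, 2, max))
  }
  drop(pooled %*% params$W_P) + params$b_P
}

## Brute-force top-k sparse attention oracle: full score vector, explicit
## sort, softmax over the kept scores, weighted row sum.
sparseAttentionOracle <- function(zStruct, H, params) {
  cfg <- params$config
  zp <- drop(zStruct %*% params$proj_W) + params$proj_b
  q <- drop(params$W_Q %*% zp)
  dHead <- cfg$dKg / cfg$nHeads
  out <- numeric(cfg$dKg)
  for (h in seq_len(cfg$nHeads)) {
    cols <- ((h - 1) * dHead + 1):(h * dHead)
    scores <- numeric(nrow(H))
    for (i in seq_len(nrow(H)))
      scores[i] <- sum((H[i, ] %*% t(params$W_K))[cols] * q[cols]) /
        sqrt(dHead)
    kUse <- min(cfg$k, nrow(H))
    sel <- order(-scores, seq_len(nrow(H)))[seq_len(kUse)]
    e <- exp(scores[sel] - max(scores[sel]))
    w <- e / sum(e)
    acc <- numeric(length(cols))
    for (j in seq_along(sel)) acc <- acc + w[j] * H[sel[j], cols]
    out[cols] <- acc
  }
  out
}

## Dense attention (no top-k) oracle.
denseAttentionOracle <- function(zStruct, H, params) {
  p2 <- params
  p2$config$k <- nrow(H)
  sparseAttentionOracle(zStruct, H, p2)
}

## All-pairs AUROC oracle: concordant pair counting with half-credit ties.
aurocOracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

## Threshold-sweep AUPR oracle.
auprOracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / sum(labels == 1)
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}

## Dense Chebyshev polynomial recurrence oracle for spectral propagation.
spectralOracle <- function(X, A, order, theta, mu) {
  A <- as.matrix(A)
  n <- nrow(A)
  deg <- rowSums(A)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Ahat <- diag(inv) %*% A %*% diag(inv)
  k <- 0:order
  muc <- max(-1, min(1, mu))
  cs <- (2 - (k == 0)) * exp(-theta) * besselI(theta, k) *
    cos(k * acos(muc))
  if (order == 0 || sum(A != 0) == 0) return(cs[1] * X)
  Tm <- list(diag(n), Ahat)
  H <- cs[1] * X + cs[2] * (Ahat %*% X)
  if (order >= 2) for (kk in 2:order) {
    Tm[[kk + 1]] <- 2 * Ahat %*% Tm[[kk]] - Tm[[kk - 1]]
    H <- H + cs[kk + 1] * (Tm[[kk + 1]] %*% X)
  }
  H
}

## Tiny deterministic knowledge base fixture.
toyKb <- function() {
  knowledgeBase(
    h = c("d1", "d1", "d2", "p1", "d3"),
    r = c("binds", "binds", "interacts", "interacts", "binds"),
    t = c("p1", "p2", "p1", "p2", "p3"))
}

## A small corpus shared by slower tests (built once per test session).
sharedCorpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCorpus(nDrugs = 40, nProteins = 25, B = 4,
                               pIn = 0.3, pOut = 0.02, fMiss = 0.2,
                               seed = 42)
    cache
  }
})
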