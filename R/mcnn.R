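## Multiscale convolutional encoder for protein sequences.
##
## Residues are embedded to an m x embedDim matrix; three branches apply
## one, two and three stacked 1-D convolutions (kernel length 3, valid
## padding, ReLU after each); each branch is max-pooled over the sequence
## axis; the concatenated branch outputs are mapped by an affine layer to
## the fixed 128-d protein structure feature.
##
## Sequences shorter than the deepest receptive field (7 residues) are
## right-padded with a dedicated trainable pad symbol; pad positions
## participate in the max-pool.

MCNN_KERNEL <- 3L
MCNN_OUT_DIM <- 128L

#' Parameters of the multiscale CNN protein structure encoder
#'
#' @param embedDim residue embedding width (default 128).
#' @param channels output channels of every convolution; branch outputs
#'   concatenate to `3 * channels`, which fixes the input width of the
#'   output projection (384 at the default).
#' @param seed seed for weight initialization.
#' @param init `"glorot"` or `"zero"`.
#' @param layerNorm apply a trainable layer normalization to the 128-d
#'   output feature (default `FALSE`). Bounds the protein channel's scale
#'   during end-to-end training; deterministic at evaluation.
#' @return named list of parameter arrays plus a `config` element.
#' @export
mcnnParams <- function(embedDim = 128L, channels = 128L, seed = 1L,
                       init = c("glorot", "zero"), layerNorm = FALSE) {
  init <- match.arg(init)
  set.seed(seed)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else glorot(nr, nc)
  }
  nRes <- length(aminoAcidAlphabet()) + 1L  # + pad symbol
  p <- list(res_embed = mk(nRes, embedDim))
  for (br in 1:3) {
    for (l in seq_len(br)) {
      din <- if (l == 1L) embedDim else channels
      p[[sprintf("conv_W_%d_%d", br, l)]] <- mk(MCNN_KERNEL * din, channels)
      p[[sprintf("conv_b_%d_%d", br, l)]] <- zerosVec(channels)
    }
  }
  p$W_P <- mk(3L * channels, MCNN_OUT_DIM)
  p$b_P <- zerosVec(MCNN_OUT_DIM)
  if (layerNorm) {
    p$ln_gamma <- rep(1, MCNN_OUT_DIM)
    p$ln_beta <- zerosVec(MCNN_OUT_DIM)
  }
  p$config <- list(embedDim = embedDim, channels = channels,
                   kernel = MCNN_KERNEL, outDim = MCNN_OUT_DIM,
                   layerNorm = layerNorm)
  p
}

## Residue indices with right-padding to minLen; pad index is the extra row.
mcnnResidueIndices <- function(seq, minLen = 7L) {
  alpha <- aminoAcidAlphabet()
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, alpha, nomatch = match("X", alpha))
  if (length(idx) < minLen)
    idx <- c(idx, rep(length(alpha) + 1L, minLen - length(idx)))
  idx
}

#' Encode a protein sequence into the 128-d structure feature
#'
#' @param seq a [ProteinSequence-class] or plain residue string.
#' @param params parameters from [mcnnParams()].
#' @return numeric vector of length 128.
#' @export
encodeProtein <- function(seq, params) {
  encodeProteinForward(seq, params)$z
}

encodeProteinForward <- function(seq, params) {
  if (is(seq, "ProteinSequence")) seq <- residues(seq)
  fw <- encodeProteinsForward(list(mcnnResidueIndices(seq)), params)
  fw$z <- fw$Z[1, ]
  fw
}

encodeProteinBackward <- function(dz, fw, params) {
  encodeProteinsBackward(matrix(dz, nrow = 1L), fw, params)
}

## Sliding-window row indices for a batch of stacked sequences: windows
## never cross sequence boundaries, so the stacked valid convolution is a
## single dense product over all sequences at once.
stackWindows <- function(lens) {
  starts <- cumsum(c(1L, lens[-length(lens)]))
  w0 <- unlist(mapply(function(s, l) if (l >= MCNN_KERNEL)
    s:(s + l - MCNN_KERNEL) else integer(),
    starts, lens, SIMPLIFY = FALSE))
  list(w0 = w0, outLens = pmax(lens - MCNN_KERNEL + 1L, 0L))
}

## The kernel-3 convolution is computed as three shifted matmuls of the
## full stacked input against the kernel's row blocks: no unfold matrix
## is materialized.
convBatchForward <- function(X, lens, W, b) {
  sw <- stackWindows(lens)
  din <- ncol(X)
  w0 <- sw$w0
  nX <- nrow(X)
  ## shift-and-add, then a single row selection
  S <- X %*% W[1:din, , drop = FALSE]
  XW2 <- X %*% W[(din + 1L):(2L * din), , drop = FALSE]
  XW3 <- X %*% W[(2L * din + 1L):(3L * din), , drop = FALSE]
  S[1:(nX - 1L), ] <- S[1:(nX - 1L), , drop = FALSE] +
    XW2[2:nX, , drop = FALSE]
  S[1:(nX - 2L), ] <- S[1:(nX - 2L), , drop = FALSE] +
    XW3[3:nX, , drop = FALSE]
  A <- S[w0, , drop = FALSE]
  A <- A + rep(b, each = nrow(A))
  pos <- A > 0
  list(Y = A * pos, A = A, pos = pos, X = X, w0 = w0, inRows = nrow(X),
       outLens = sw$outLens)
}

convBatchBackward <- function(dY, cache, W) {
  dA <- dY * cache$pos
  din <- ncol(cache$X)
  dX <- matrix(0, cache$inRows, din)
  dW <- matrix(0, MCNN_KERNEL * din, ncol(dA))
  for (j in seq_len(MCNN_KERNEL)) {
    rows <- ((j - 1L) * din + 1L):(j * din)
    sel <- cache$w0 + (j - 1L)   # unique rows: scatter is an assignment
    dW[rows, ] <- crossprod(cache$X[sel, , drop = FALSE], dA)
    dX[sel, ] <- dX[sel, , drop = FALSE] +
      tcrossprod(dA, W[rows, , drop = FALSE])
  }
  list(dW = dW, db = colSums(dA), dX = dX)
}

## Batched forward over a list of residue index vectors.
encodeProteinsForward <- function(idxList, params) {
  lens <- lengths(idxList)
  idx <- unlist(idxList)
  nSeq <- length(idxList)
  ch <- params$config$channels
  E <- params$res_embed[idx, , drop = FALSE]
  branches <- vector("list", 3L)
  argmax <- vector("list", 3L)
  pooled <- matrix(0, nSeq, 3L * ch)
  for (br in 1:3) {
    X <- E
    curLens <- lens
    caches <- vector("list", br)
    for (l in seq_len(br)) {
      caches[[l]] <- convBatchForward(
        X, curLens, params[[sprintf("conv_W_%d_%d", br, l)]],
        params[[sprintf("conv_b_%d_%d", br, l)]])
      X <- caches[[l]]$Y
      curLens <- caches[[l]]$outLens
    }
    branches[[br]] <- caches
    ## per-sequence max-pool over the sequence axis
    ends <- cumsum(curLens)
    starts <- ends - curLens + 1L
    am <- matrix(0L, nSeq, ch)
    for (s in seq_len(nSeq)) {
      block <- X[starts[s]:ends[s], , drop = FALSE]
      rowsMax <- max.col(t(block), ties.method = "first")
      am[s, ] <- rowsMax + starts[s] - 1L
      pooled[s, (br - 1L) * ch + seq_len(ch)] <-
        block[cbind(rowsMax, seq_len(ch))]
    }
    argmax[[br]] <- am
  }
  Z <- denseForward(pooled, params$W_P, params$b_P)
  ln <- NULL
  if (isTRUE(params$config$layerNorm)) {
    ln <- layerNormForward(Z, params$ln_gamma, params$ln_beta)
    Z <- ln$Y
  }
  list(Z = Z, idx = idx, lens = lens, E = E, branches = branches,
       argmax = argmax, pooled = pooled, ln = ln)
}

encodeProteinsBackward <- function(dZ, fw, params) {
  grads <- list()
  if (!is.null(fw$ln)) {
    bln <- layerNormBackward(dZ, fw$ln, params$ln_gamma)
    grads$ln_gamma <- bln$dgamma
    grads$ln_beta <- bln$dbeta
    dZ <- bln$dX
  }
  bkP <- denseBackward(fw$pooled, params$W_P, dZ)
  grads$W_P <- bkP$dW
  grads$b_P <- bkP$db
  ch <- params$config$channels
  nSeq <- length(fw$lens)
  dE <- matrix(0, nrow(fw$E), ncol(fw$E))
  for (br in 1:3) {
    caches <- fw$branches[[br]]
    top <- caches[[br]]$Y
    dY <- matrix(0, nrow(top), ncol(top))
    am <- fw$argmax[[br]]
    cols <- rep(seq_len(ch), each = nSeq)
    dY[cbind(as.vector(am), cols)] <-
      as.vector(bkP$dX[, (br - 1L) * ch + seq_len(ch), drop = FALSE])
    for (l in rev(seq_len(br))) {
      bk <- convBatchBackward(dY, caches[[l]],
                              params[[sprintf("conv_W_%d_%d", br, l)]])
      grads[[sprintf("conv_W_%d_%d", br, l)]] <- bk$dW
      grads[[sprintf("conv_b_%d_%d", br, l)]] <- bk$db
      dY <- bk$dX
    }
    dE <- dE + dY
  }
  nRes <- length(aminoAcidAlphabet()) + 1L
  grads$res_embed <- rowsumInto(dE, fw$idx, nRes)
  grads
}
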