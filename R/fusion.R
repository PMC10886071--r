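## Task-specific feature fusion and the prediction head.
##
## Per-modality features are affine-projected with dropout and
## concatenated:
##   z_S  = Dropout(W_S  (z_S^left  [+] z_S^right)  + b_S)
##   z_SK = Dropout(W_SK (z_SK^left [+] z_SK^right) + b_SK)
##   z_UK = text head on the single text (DP) or the [SEP]-joined pair,
## then y-hat = sigmoid(MLP(z_S [+] z_SK [+] z_UK)) with a per-label
## binary cross-entropy loss. Pair concatenations are ordered (DDI with
## drugs (A,B) differs from (B,A) in general).

taskArity <- function(task) if (task == "DP") 1L else 2L

#' Sides of each prediction task
#'
#' @param task task tag.
#' @return character vector of `"drug"`/`"protein"` per side.
#' @export
taskSides <- function(task) {
  switch(task,
         DTI = c("drug", "protein"),
         DP  = "drug",
         DDI = c("drug", "drug"),
         PPI = c("protein", "protein"),
         stop("unknown task: ", task))
}

#' Parameters of the per-task fusion layer
#'
#' @param task task tag (fixes the concatenation arity: 1 for DP, 2
#'   otherwise).
#' @param dStructIn total width of the concatenated structure features.
#' @param dSKIn total width of the concatenated structured-knowledge
#'   features (arity x dKg).
#' @param dS,dSKOut output widths (default 256 each).
#' @param dropoutRate dropout probability, active in training mode only.
#' @param seed,init initialization controls.
#' @return named list with `W_S`, `b_S`, `W_SK`, `b_SK`, `dropoutRate`,
#'   `config`.
#' @export
fusionParams <- function(task, dStructIn, dSKIn, dS = 256L, dSKOut = 256L,
                         dropoutRate = 0.1, seed = 1L,
                         init = c("glorot", "zero")) {
  init <- match.arg(init)
  set.seed(seed)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else glorot(nr, nc)
  }
  list(W_S = mk(dStructIn, dS), b_S = zerosVec(dS),
       W_SK = mk(dSKIn, dSKOut), b_SK = zerosVec(dSKOut),
       dropoutRate = dropoutRate,
       config = list(task = task, dStructIn = dStructIn, dSKIn = dSKIn,
                     dS = dS, dSKOut = dSKOut))
}

#' Fuse per-modality features for one sample
#'
#' @param task task tag.
#' @param left list with `zStruct`, `zSK`, `text` for the left biomolecule.
#' @param right same for the right biomolecule (pair tasks only).
#' @param params fusion parameters from [fusionParams()].
#' @param backbone,textHead unstructured-knowledge encoder components.
#' @param training logical; enables dropout.
#' @return list with `zS`, `zSK`, `zUK`.
#' @export
fuseFeatures <- function(task, left, right = NULL, params, backbone,
                         textHead, training = FALSE) {
  arity <- taskArity(task)
  if (arity == 2L && is.null(right))
    stop("task ", task, " requires a right-side biomolecule")
  if (arity == 1L && !is.null(right))
    stop("task DP takes a single biomolecule")
  sIn <- c(left$zStruct, if (arity == 2L) right$zStruct)
  kIn <- c(left$zSK, if (arity == 2L) right$zSK)
  if (length(sIn) != params$config$dStructIn)
    stop("structure concatenation width ", length(sIn),
         " does not match fusion input ", params$config$dStructIn)
  zS <- drop(denseForward(matrix(sIn, nrow = 1L), params$W_S, params$b_S))
  zSK <- drop(denseForward(matrix(kIn, nrow = 1L), params$W_SK,
                           params$b_SK))
  zS <- drop(dropoutForward(matrix(zS, 1L), params$dropoutRate,
                            training)$Y)
  zSK <- drop(dropoutForward(matrix(zSK, 1L), params$dropoutRate,
                             training)$Y)
  tokens <- if (arity == 2L)
    joinPairText(left$text, right$text, backbone)
  else singleText(left$text, backbone)
  zUK <- encodeText(tokens, backbone, textHead, training)
  list(zS = zS, zSK = zSK, zUK = zUK)
}

#' Parameters of the multilayer-perceptron prediction head
#'
#' @param dIn input width (`dS + dSKOut + dUK`).
#' @param hidden integer vector of hidden widths (default `c(512, 256)`),
#'   ReLU between layers.
#' @param nLabels output width; one sigmoid per label.
#' @param seed,init initialization controls.
#' @return named list of layer weights plus `config`.
#' @export
predictionHead <- function(dIn, hidden = c(512L, 256L), nLabels = 1L,
                           seed = 1L, init = c("glorot", "zero")) {
  init <- match.arg(init)
  set.seed(seed)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else glorot(nr, nc)
  }
  widths <- c(dIn, hidden, nLabels)
  p <- list()
  nl <- length(widths) - 1L
  for (l in seq_len(nl)) {
    ## the output layer starts at zero so training begins at p = 0.5
    ## with well-scaled gradients (the hidden layers break the symmetry)
    p[[paste0("W", l)]] <- if (l == nl) matrix(0, widths[l], widths[l + 1L])
                           else mk(widths[l], widths[l + 1L])
    p[[paste0("b", l)]] <- zerosVec(widths[l + 1L])
  }
  p$config <- list(widths = widths, nLayers = length(widths) - 1L)
  p
}

mlpForward <- function(X, head) {
  nl <- head$config$nLayers
  caches <- vector("list", nl)
  for (l in seq_len(nl)) {
    A <- denseForward(X, head[[paste0("W", l)]], head[[paste0("b", l)]])
    caches[[l]] <- list(X = X, A = A)
    X <- if (l < nl) relu(A) else A
  }
  list(logits = X, caches = caches)
}

mlpBackward <- function(dLogits, fw, head) {
  nl <- head$config$nLayers
  grads <- list()
  dA <- dLogits
  for (l in rev(seq_len(nl))) {
    cache <- caches <- fw$caches[[l]]
    if (l < nl) dA <- dA * (cache$A > 0)
    bk <- denseBackward(cache$X, head[[paste0("W", l)]], dA)
    grads[[paste0("W", l)]] <- bk$dW
    grads[[paste0("b", l)]] <- bk$db
    dA <- bk$dX
  }
  list(grads = grads, dX = dA)
}

#' Predict label probabilities from fused features
#'
#' @param zS,zSK,zUK fused modality features for one sample.
#' @param head parameters from [predictionHead()].
#' @return numeric vector of probabilities in (0, 1), length `nLabels`.
#' @export
predictProbs <- function(zS, zSK, zUK, head) {
  x <- matrix(c(zS, zSK, zUK), nrow = 1L)
  if (ncol(x) != head$config$widths[1])
    stop("fused feature width ", ncol(x),
         " does not match head input ", head$config$widths[1])
  drop(sigmoid(mlpForward(x, head)$logits))
}

#' Masked binary cross-entropy loss
#'
#' Mean over unmasked labels of `-(y log yhat + (1-y) log(1-yhat))`, with
#' predictions clipped to `[eps, 1-eps]` to keep the loss finite. Missing
#' labels (`NA` in `y`, or 0 in `mask`) are excluded.
#'
#' @param yhat predicted probabilities (vector or matrix).
#' @param y ground-truth 0/1 labels, `NA` allowed.
#' @param mask optional 0/1 mask of the same shape (1 = keep).
#' @param eps clipping constant (default `1e-7`).
#' @return scalar loss.
#' @export
bceLoss <- function(yhat, y, mask = NULL, eps = 1e-7) {
  if (length(yhat) != length(y))
    stop("yhat and y must have the same length")
  keep <- !is.na(y)
  if (!is.null(mask)) {
    if (length(mask) != length(y))
      stop("mask must have the same length as y")
    keep <- keep & (mask != 0)
  }
  if (!any(keep)) stop("all labels are masked; loss is undefined")
  p <- pmin(pmax(yhat[keep], eps), 1 - eps)
  yy <- y[keep]
  -mean(yy * log(p) + (1 - yy) * log(1 - p))
}
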