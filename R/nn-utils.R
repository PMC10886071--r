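## Small neural-network primitives used by the encoders and the fusion
## predictor: dense layers with explicit backward passes, inverted dropout,
## and an Adam optimizer over flat named parameter lists. All arrays are
## base-R matrices; forward functions return caches for the backward pass.

## Glorot-uniform init, seeded by the caller via set.seed().
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

zerosVec <- function(n) numeric(n)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## Dense layer: X (n x din) %*% W (din x dout) + b. Backward returns grads
## and the input gradient.
denseForward <- function(X, W, b) {
  Y <- X %*% W
  ## column-major recycling adds b_j to column j without a sweep()
  Y + rep(b, each = nrow(Y))
}

denseBackward <- function(X, W, dY) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, W))
}

## Inverted dropout: scaling at train time so eval is the identity.
dropoutForward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(rbinom(length(X), 1L, 1 - rate), nrow(X), ncol(X)) /
    (1 - rate)
  list(Y = X * mask, mask = mask)
}

dropoutBackward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

## Per-row layer normalization with trainable gain/offset.
layerNormForward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  Y <- Xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(Y = Y, Xhat = Xhat, inv = inv)
}

layerNormBackward <- function(dY, cache, gamma) {
  d <- ncol(dY)
  dXhat <- dY * rep(gamma, each = nrow(dY))
  rowDot <- rowSums(dXhat * cache$Xhat) / d
  rowMean <- rowMeans(dXhat)
  dX <- (dXhat - rowMean - cache$Xhat * rowDot) * cache$inv
  list(dX = dX, dgamma = colSums(dY * cache$Xhat), dbeta = colSums(dY))
}

softmaxVec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## d/dx of softmax applied to upstream gradient g: s * (g - sum(g*s)).
softmaxBackward <- function(s, g) {
  s * (g - sum(g * s))
}

## Stable sigmoid.
sigmoid <- function(x) {
  out <- x
  p <- x >= 0
  out[p] <- 1 / (1 + exp(-x[p]))
  e <- exp(x[!p])
  out[!p] <- e / (1 + e)
  out
}

#' Adam optimizer state for a named parameter list
#'
#' @param params named list of numeric arrays.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param weightDecay L2 coefficient added to every gradient
#'   (default `1e-6`).
#' @return an opaque optimizer state list for [adamStep()].
#' @export
adamInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 1e-6) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       wd = weightDecay, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

#' One Adam update over a named parameter list
#'
#' Parameters present in `params` but absent from `grads` (or frozen by
#' `freeze`) are left untouched.
#'
#' @param params named list of numeric arrays.
#' @param grads named list of gradients (same shapes).
#' @param state state from [adamInit()].
#' @param freeze character vector of parameter names to skip.
#' @return list with updated `params` and `state`.
#' @export
adamStep <- function(params, grads, state, freeze = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% freeze || is.null(params[[nm]])) next
    g <- grads[[nm]] + state$wd * params[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

## Accumulate gradient lists (named), summing shared names.
accumulateGrads <- function(acc, g) {
  for (nm in names(g)) {
    if (is.null(acc[[nm]])) acc[[nm]] <- g[[nm]]
    else acc[[nm]] <- acc[[nm]] + g[[nm]]
  }
  acc
}

## Derive a child seed from a root seed and a tag, kept within 32-bit range.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
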