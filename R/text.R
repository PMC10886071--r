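## Unstructured-knowledge encoder: a pluggable text backbone producing
## per-token vectors whose position 0 is the [CLS] summary, followed by an
## affine head with dropout on the [CLS] row.
##
## Two backbones ship:
##  * "toy": whitespace/punctuation tokenizer with a trainable token
##    embedding table; the [CLS] row is the mean of the segment token
##    embeddings. Deterministic, CPU-fast, used throughout the test suite,
##    and order-invariant within a segment by construction.
##  * "external": an adapter contract for any pretrained transformer that
##    exposes [CLS] vectors (width 768); see [externalBackbone()].

TOK_CLS <- 1L
TOK_SEP <- 2L
TOK_PAD <- 3L
TOK_UNK <- 4L
N_RESERVED <- 4L

#' Tokenize a string with the toy tokenizer
#'
#' Lowercases, splits on whitespace and punctuation, and maps tokens
#' through the backbone vocabulary (unknowns to the reserved `[UNK]` id).
#'
#' @param text a string.
#' @param backbone a backbone from [toyBackbone()].
#' @return integer token ids (no `[CLS]`/`[SEP]` added).
#' @export
tokenizeText <- function(text, backbone) {
  if (is.na(text) || !nzchar(text)) return(integer())
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  ids <- match(toks, backbone$vocab) + N_RESERVED
  ids[is.na(ids)] <- TOK_UNK
  ids
}

#' Toy text backbone
#'
#' @param texts character vector the vocabulary is built from.
#' @param dText embedding width (default 64; a full-scale transformer
#'   backbone would use 768).
#' @param maxLen maximum token-sequence length including `[CLS]`/`[SEP]`
#'   (default 512).
#' @param seed seed for the embedding table.
#' @param init `"glorot"` or `"zero"`.
#' @return a backbone list: `vocab`, `dText`, `maxLen`, and the trainable
#'   parameter list `params$tok_embed` (rows: reserved ids then vocabulary).
#' @export
toyBackbone <- function(texts = character(), dText = 64L, maxLen = 512L,
                        seed = 1L, init = c("glorot", "zero")) {
  init <- match.arg(init)
  toks <- unlist(strsplit(tolower(texts), "[^a-z0-9]+"))
  vocab <- sort(unique(toks[nzchar(toks)]))
  set.seed(seed)
  n <- N_RESERVED + length(vocab)
  ## unit-variance rows (the embedding-table convention): mean pooling
  ## over L tokens then gives [CLS] entries of scale ~ 1/sqrt(L), which
  ## keeps the text channel commensurate with the other modalities
  emb <- if (init == "zero") matrix(0, n, dText)
         else matrix(rnorm(n * dText), n, dText)
  emb[TOK_PAD, ] <- 0
  list(kind = "toy", vocab = vocab, dText = dText, maxLen = maxLen,
       params = list(tok_embed = emb))
}

#' Adapter contract for an external pretrained backbone
#'
#' Wraps user-supplied `tokenize(text) -> ids` and `encode(ids) -> matrix`
#' closures (position 0 of the output must be the `[CLS]` vector) into the
#' backbone interface. Nothing in the package requires pretrained weights;
#' this is the injection point for them.
#'
#' @param tokenize function mapping a string to integer ids.
#' @param encode function mapping ids to an L x dText matrix.
#' @param dText output width (768 for the usual transformer backbones).
#' @param maxLen maximum length.
#' @return a backbone list.
#' @export
externalBackbone <- function(tokenize, encode, dText = 768L,
                             maxLen = 512L) {
  list(kind = "external", tokenize = tokenize, encode = encode,
       dText = dText, maxLen = maxLen, params = list())
}

#' Join a pair of texts into one token sequence
#'
#' Produces `[CLS] tokens(a) [SEP] tokens(b)`, truncated to the backbone's
#' `maxLen`. Truncation keeps the head of each segment, shrinking the two
#' segments proportionally to their lengths.
#'
#' @param textA,textB strings (either may be empty).
#' @param backbone a backbone from [toyBackbone()].
#' @return integer token-id sequence starting with `[CLS]`.
#' @export
joinPairText <- function(textA, textB, backbone) {
  a <- tokenizeText(textA, backbone)
  b <- tokenizeText(textB, backbone)
  budget <- backbone$maxLen - 2L  # [CLS] and [SEP]
  if (length(a) + length(b) > budget) {
    tot <- length(a) + length(b)
    keepA <- floor(budget * length(a) / tot)
    keepB <- budget - keepA
    if (keepB > length(b)) { keepA <- keepA + (keepB - length(b))
                             keepB <- length(b) }
    if (keepA > length(a)) { keepB <- keepB + (keepA - length(a))
                             keepA <- length(a) }
    a <- head(a, keepA)
    b <- head(b, keepB)
  }
  c(TOK_CLS, a, TOK_SEP, b)
}

#' Single-text token sequence
#'
#' `[CLS] tokens(text)`, truncated to `maxLen`.
#'
#' @inheritParams joinPairText
#' @param text a string.
#' @return integer token-id sequence starting with `[CLS]`.
#' @export
singleText <- function(text, backbone) {
  a <- tokenizeText(text, backbone)
  c(TOK_CLS, head(a, backbone$maxLen - 1L))
}

#' Parameters of the unstructured-knowledge head
#'
#' @param dText backbone output width.
#' @param dUK output width of the unstructured-knowledge feature
#'   (default 256).
#' @param dropoutRate dropout probability (applied in training mode only).
#' @param seed seed for initialization.
#' @param init `"glorot"` or `"zero"`.
#' @return named list: `W_UK` (dText x dUK), `b_UK`, `dropoutRate`.
#' @export
textHeadParams <- function(dText, dUK = 256L, dropoutRate = 0.1,
                           seed = 1L, init = c("glorot", "zero")) {
  init <- match.arg(init)
  set.seed(seed)
  W <- if (init == "zero") matrix(0, dText, dUK) else glorot(dText, dUK)
  list(W_UK = W, b_UK = zerosVec(dUK), dropoutRate = dropoutRate)
}

## Toy backbone forward: [CLS] row = mean embedding of non-reserved,
## non-pad tokens (all-reserved sequences give a zero [CLS] row).
toyEncodeForward <- function(tokens, backbone) {
  emb <- backbone$params$tok_embed
  content <- tokens[tokens != TOK_CLS & tokens != TOK_SEP &
                      tokens != TOK_PAD]
  h1 <- if (length(content))
    colMeans(emb[content, , drop = FALSE]) else numeric(backbone$dText)
  list(h1 = h1, content = content)
}

#' Encode a token sequence into the unstructured-knowledge feature
#'
#' `z_UK = Dropout(W_UK h_1 + b_UK)` where `h_1` is the backbone's `[CLS]`
#' output. With `training = FALSE` dropout is the identity and the result
#' is a pure function of tokens and weights.
#'
#' @param tokens integer token ids beginning with `[CLS]`.
#' @param backbone a backbone list.
#' @param head parameters from [textHeadParams()].
#' @param training logical; enables dropout.
#' @return numeric vector of length `dUK`.
#' @export
encodeText <- function(tokens, backbone, head, training = FALSE) {
  encodeTextForward(tokens, backbone, head, training)$z
}

encodeTextForward <- function(tokens, backbone, head, training = FALSE) {
  if (length(tokens) == 0L || tokens[1] != TOK_CLS)
    stop("token sequence must begin with [CLS]")
  if (backbone$kind == "toy") {
    bb <- toyEncodeForward(tokens, backbone)
    h1 <- bb$h1
    content <- bb$content
  } else {
    H <- backbone$encode(tokens)
    h1 <- H[1, ]
    content <- integer()
  }
  if (length(h1) != nrow(head$W_UK))
    stop("backbone width ", length(h1), " does not match head input width ",
         nrow(head$W_UK))
  pre <- drop(denseForward(matrix(h1, nrow = 1L), head$W_UK, head$b_UK))
  dp <- dropoutForward(matrix(pre, nrow = 1L), head$dropoutRate, training)
  list(z = drop(dp$Y), h1 = h1, content = content, mask = dp$mask)
}

encodeTextBackward <- function(dz, fw, backbone, head) {
  dPre <- dropoutBackward(matrix(dz, nrow = 1L), fw$mask)
  bk <- denseBackward(matrix(fw$h1, nrow = 1L), head$W_UK, dPre)
  grads <- list(W_UK = bk$dW, b_UK = bk$db)
  if (backbone$kind == "toy" && length(fw$content)) {
    dh1 <- drop(bk$dX) / length(fw$content)
    gEmb <- matrix(0, nrow(backbone$params$tok_embed), backbone$dText)
    add <- rowsumInto(matrix(rep(dh1, each = length(fw$content)),
                             nrow = length(fw$content)),
                      fw$content, nrow(gEmb))
    grads$tok_embed <- gEmb + add
  }
  grads
}
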