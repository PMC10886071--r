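## End-to-end model bundle and training loop.
##
## A model is a flat named list of parameter arrays (prefixes: gin., mcnn.,
## txt., sa_d., sa_p., fus., head.) plus frozen context (knowledge store,
## knowledge-graph embedding matrix, backbone vocabulary, configuration).
## Structure encoders run once per unique biomolecule per batch; their
## outputs are shared across rows and gradients are accumulated per unique
## biomolecule before a single backward pass, which keeps desk-scale
## training fast without changing the mathematics.

#' Training/model configuration
#'
#' Defaults are the desk-scale configuration used throughout the package
#' examples and tests; component-level constructors keep their own
#' full-scale defaults. All randomness (initialization, shuffling, dropout,
#' modality masking) derives from `seed`.
#'
#' @param ginLayers,nodeEmbedDim,ginHidden drug encoder dimensions.
#' @param ginLayerNorm per-layer normalization in the drug encoder
#'   (default `TRUE`); keeps node-feature scales bounded during
#'   end-to-end training.
#' @param mcnnEmbed,mcnnChannels protein encoder dimensions (output is
#'   always 128).
#' @param mcnnLayerNorm layer normalization on the protein output
#'   feature (default `TRUE`).
#' @param dText,dUK,textDropout unstructured-knowledge encoder dimensions.
#' @param dS,dSKOut,fusionDropout fusion projection widths and dropout.
#' @param mlpHidden hidden widths of the prediction head.
#' @param nHeads,k sparse-attention heads and top-k (defaults 4 and 16).
#' @param maskP modality masking probability during training (default
#'   0.05; evaluation always uses 0).
#' @param reconstruct `"sparse"` for sparse-attention reconstruction of
#'   missing structured knowledge, `"zero"` for the zero-imputation
#'   ablation variant.
#' @param lr,weightDecay Adam learning rate and weight decay (default
#'   `1e-2` and `1e-6`).
#' @param clipNorm global gradient-norm clipping threshold (default 1;
#'   `Inf` disables). Keeps occasional loss spikes from destabilizing
#'   training at the default learning rate.
#' @param epochs,batchSize,patience training budget, minibatch size, and
#'   early-stopping patience on the validation metric.
#' @param seed root RNG seed.
#' @return a config list.
#' @export
modelConfig <- function(ginLayers = 5L, nodeEmbedDim = 120L,
                        ginHidden = 32L, ginLayerNorm = FALSE,
                        mcnnEmbed = 32L, mcnnChannels = 32L,
                        mcnnLayerNorm = FALSE, dText = 32L, dUK = 32L,
                        textDropout = 0.1, dS = 32L, dSKOut = 32L,
                        fusionDropout = 0.1, mlpHidden = c(128L, 64L),
                        nHeads = 4L, k = 16L, maskP = 0.05,
                        reconstruct = c("sparse", "zero"), lr = 1e-2,
                        weightDecay = 1e-6, clipNorm = 1,
                        epochs = 30L, batchSize = 128L, patience = 6L,
                        seed = 1L) {
  list(ginLayers = ginLayers, nodeEmbedDim = nodeEmbedDim,
       ginHidden = ginHidden, ginLayerNorm = ginLayerNorm,
       mcnnEmbed = mcnnEmbed, mcnnChannels = mcnnChannels,
       mcnnLayerNorm = mcnnLayerNorm, dText = dText, dUK = dUK,
       textDropout = textDropout, dS = dS, dSKOut = dSKOut,
       fusionDropout = fusionDropout, mlpHidden = mlpHidden,
       nHeads = nHeads, k = k, maskP = maskP,
       reconstruct = match.arg(reconstruct), lr = lr,
       weightDecay = weightDecay, clipNorm = clipNorm, epochs = epochs,
       batchSize = batchSize, patience = patience, seed = seed)
}

prefixParams <- function(p, prefix) {
  p$config <- NULL
  names(p) <- paste0(prefix, ".", names(p))
  p
}

subParams <- function(flat, prefix, config = NULL) {
  sel <- grep(paste0("^", prefix, "\\."), names(flat), value = TRUE)
  p <- flat[sel]
  names(p) <- sub(paste0("^", prefix, "\\."), "", names(p))
  p$config <- config
  p
}

structWidth <- function(kind, config) {
  if (kind == "drug") config$ginHidden else MCNN_OUT_DIM
}

#' Initialize a model bundle for a task
#'
#' @param task `"DTI"`, `"DP"`, `"DDI"` or `"PPI"`.
#' @param store a [KnowledgeStore-class].
#' @param kgEmb a [KgEmbedding-class] (computed with test links removed
#'   when the model will be evaluated).
#' @param nLabels number of output labels (1 for DTI/DP-per-task/DDI;
#'   number of relation types for PPI).
#' @param config configuration from [modelConfig()].
#' @return a model bundle list (`params`, `configs`, context, caches).
#' @export
modelInit <- function(task, store, kgEmb, nLabels = 1L,
                      config = modelConfig()) {
  sides <- taskSides(task)
  dKg <- ncol(embeddingMatrix(kgEmb))
  if (dKg %% config$nHeads != 0L)
    stop("knowledge-graph width ", dKg, " must be divisible by nHeads")
  seed <- config$seed
  backbone <- toyBackbone(texts = unname(store@texts),
                          dText = config$dText,
                          seed = deriveSeed(seed, "backbone"))
  flat <- list()
  configs <- list()
  if ("drug" %in% sides) {
    gp <- ginParams(config$ginLayers, config$nodeEmbedDim,
                    config$ginHidden, seed = deriveSeed(seed, "gin"),
                    layerNorm = isTRUE(config$ginLayerNorm))
    configs$gin <- gp$config
    flat <- c(flat, prefixParams(gp, "gin"))
    sad <- sparseAttentionParams(config$ginHidden, dKg,
                                 nHeads = config$nHeads, k = config$k,
                                 seed = deriveSeed(seed, "sa_d"))
    configs$sa_d <- sad$config
    flat <- c(flat, prefixParams(sad, "sa_d"))
  }
  if ("protein" %in% sides) {
    mp <- mcnnParams(config$mcnnEmbed, config$mcnnChannels,
                     seed = deriveSeed(seed, "mcnn"),
                     layerNorm = isTRUE(config$mcnnLayerNorm))
    configs$mcnn <- mp$config
    flat <- c(flat, prefixParams(mp, "mcnn"))
    sap <- sparseAttentionParams(MCNN_OUT_DIM, dKg,
                                 nHeads = config$nHeads, k = config$k,
                                 seed = deriveSeed(seed, "sa_p"))
    configs$sa_p <- sap$config
    flat <- c(flat, prefixParams(sap, "sa_p"))
  }
  th <- textHeadParams(config$dText, config$dUK,
                       dropoutRate = config$textDropout,
                       seed = deriveSeed(seed, "texthead"))
  flat$txt.tok_embed <- backbone$params$tok_embed
  flat$txt.W_UK <- th$W_UK
  flat$txt.b_UK <- th$b_UK
  dStructIn <- sum(vapply(sides, structWidth, 0, config = config))
  dSKIn <- length(sides) * dKg
  fp <- fusionParams(task, dStructIn, dSKIn, dS = config$dS,
                     dSKOut = config$dSKOut,
                     dropoutRate = config$fusionDropout,
                     seed = deriveSeed(seed, "fusion"))
  configs$fus <- fp$config
  flat <- c(flat, prefixParams(fp[c("W_S", "b_S", "W_SK", "b_SK")],
                               "fus"))
  hd <- predictionHead(config$dS + config$dSKOut + config$dUK,
                       hidden = config$mlpHidden, nLabels = nLabels,
                       seed = deriveSeed(seed, "head"))
  configs$head <- hd$config
  flat <- c(flat, prefixParams(hd, "head"))
  model <- list(task = task, config = config, configs = configs,
                store = store, kgEmb = kgEmb,
                backboneVocab = backbone$vocab, nLabels = nLabels,
                params = flat,
                graphCache = new.env(parent = emptyenv()))
  calibrateFeatureScales(model)
}

## Initialization-time channel calibration: the three modality channels
## enter fusion on very different natural scales (graph features grow with
## message-passing depth; spectral KG embeddings live near the origin).
## Each channel is divided by a fixed constant chosen once at init so its
## entries are roughly unit variance; the constants are part of the model
## and never updated, so the mathematics of the fusion equations is
## unchanged up to a reparameterization of W_S / W_SK.
calibrateFeatureScales <- function(model) {
  cfg <- model$config
  sides <- unique(taskSides(model$task))
  H <- embeddingMatrix(model$kgEmb)
  kgScale <- stats::sd(H)
  if (!is.finite(kgScale) || kgScale < 1e-12) kgScale <- 1
  model$Hs <- H / kgScale
  model$kgScale <- kgScale
  scales <- c(drug = 1, protein = 1)
  for (kind in sides) {
    keys <- if (kind == "drug") names(model$store@drugIndex)
            else names(model$store@proteinIndex)
    if (!length(keys)) next
    keys <- keys[seq_len(min(48L, length(keys)))]
    ixList <- lapply(keys, entityIndices, model = model, kind = kind)
    Z <- if (kind == "drug")
      encodeDrugsForward(ixList, subParams(model$params, "gin",
                                           model$configs$gin))$Z
    else
      encodeProteinsForward(ixList, subParams(model$params, "mcnn",
                                              model$configs$mcnn))$Z
    s <- stats::sd(Z)
    if (is.finite(s) && s > 1e-12) scales[kind] <- s
  }
  model$structScale <- scales
  model
}

modelBackbone <- function(model) {
  list(kind = "toy", vocab = model$backboneVocab,
       dText = model$config$dText, maxLen = 512L,
       params = list(tok_embed = model$params$txt.tok_embed))
}

modelSaParams <- function(model, kind) {
  pre <- if (kind == "drug") "sa_d" else "sa_p"
  subParams(model$params, pre, model$configs[[pre]])
}

## Cached featurization indices of a biomolecule (parsing/lexing is
## deterministic, so the cache never invalidates).
entityIndices <- function(model, key, kind) {
  tag <- paste0(kind, ".", key)
  ix <- get0(tag, envir = model$graphCache)
  if (is.null(ix)) {
    ix <- if (kind == "drug") ginGraphIndices(parseMolecule(key))
          else mcnnResidueIndices(key)
    assign(tag, ix, envir = model$graphCache)
  }
  ix
}

## Forward pass over a batch of rows. rows: list(left, right, labels).
## Returns loss, probabilities, and (when backward = TRUE is intended)
## every cache needed for the gradient.
batchForward <- function(model, left, right, labels, training = FALSE) {
  task <- model$task
  sides <- taskSides(task)
  cfg <- model$config
  n <- length(left)
  H <- model$Hs   # unit-variance-scaled frozen embedding matrix
  dKg <- ncol(H)
  sideKeys <- if (length(sides) == 2L) list(left, right) else list(left)
  ## unique biomolecules per kind
  uniq <- list()
  for (s in seq_along(sides)) {
    kind <- sides[s]
    uniq[[kind]] <- unique(c(uniq[[kind]], sideKeys[[s]]))
  }
  ents <- list()
  kindFw <- list()
  for (kind in names(uniq)) {
    ixList <- lapply(uniq[[kind]], entityIndices, model = model,
                     kind = kind)
    kindFw[[kind]] <- if (kind == "drug")
      encodeDrugsForward(ixList, subParams(model$params, "gin",
                                           model$configs$gin))
    else
      encodeProteinsForward(ixList, subParams(model$params, "mcnn",
                                              model$configs$mcnn))
    Z <- kindFw[[kind]]$Z
    ents[[kind]] <- lapply(seq_along(uniq[[kind]]), function(e) {
      key <- uniq[[kind]][e]
      hit <- storeLookup(model$store, key, kind)
      direct <- NULL
      txt <- ""
      txtPresent <- FALSE
      if (!isStoreMiss(hit)) {
        ri <- model$kgEmb@entityIndex[hit]
        if (!is.na(ri)) direct <- H[ri, ]
        t0 <- model$store@texts[hit]
        if (!is.na(t0)) { txt <- unname(t0); txtPresent <- TRUE }
      }
      list(key = key, kind = kind, row = e, z = Z[e, ], direct = direct,
           text = txt, textPresent = txtPresent, saFw = NULL,
           dzStruct = 0, dzRecon = NULL)
    })
    names(ents[[kind]]) <- uniq[[kind]]
  }
  ## per-row per-side masking draws (independent per record per sample)
  maskDraw <- vector("list", length(sides))
  needRecon <- list()
  for (s in seq_along(sides)) {
    kind <- sides[s]
    hasDirect <- vapply(sideKeys[[s]],
                        function(k) !is.null(ents[[kind]][[k]]$direct),
                        TRUE)
    m <- rep(FALSE, n)
    if (training && cfg$maskP > 0)
      m[hasDirect] <- runif(sum(hasDirect)) < cfg$maskP
    maskDraw[[s]] <- m
    rec <- unique(c(sideKeys[[s]][!hasDirect], sideKeys[[s]][m]))
    needRecon[[kind]] <- unique(c(needRecon[[kind]], rec))
  }
  ## sparse-attention reconstruction, batched over every unique
  ## biomolecule that needs it (store misses and masked records)
  saFwKind <- list()
  for (kind in names(needRecon)) {
    keys <- needRecon[[kind]]
    if (!length(keys)) next
    if (cfg$reconstruct == "sparse") {
      sa <- modelSaParams(model, kind)
      Zrec <- do.call(rbind, lapply(keys, function(k)
        ents[[kind]][[k]]$z))
      saFwKind[[kind]] <- saBatchForward(Zrec, H, sa)
      saFwKind[[kind]]$keys <- keys
      for (q in seq_along(keys)) {
        ents[[kind]][[keys[q]]]$recon <- saFwKind[[kind]]$Z[q, ]
        ents[[kind]][[keys[q]]]$saRow <- q
      }
    } else {
      for (k in keys) ents[[kind]][[k]]$recon <- numeric(dKg)
    }
  }
  ## assemble row-level inputs
  dStructs <- vapply(sides, structWidth, 0, config = cfg)
  ZSin <- matrix(0, n, sum(dStructs))
  ZKin <- matrix(0, n, length(sides) * dKg)
  usedRecon <- vector("list", length(sides))
  for (s in seq_along(sides)) {
    kind <- sides[s]
    sOff <- if (s == 1L) 0L else dStructs[1]
    kOff <- (s - 1L) * dKg
    rowsOf <- vapply(sideKeys[[s]], function(k) ents[[kind]][[k]]$row, 0L)
    ZSin[, sOff + seq_len(dStructs[s])] <-
      kindFw[[kind]]$Z[rowsOf, , drop = FALSE] / model$structScale[kind]
    useR <- logical(n)
    for (i in seq_len(n)) {
      e <- ents[[kind]][[sideKeys[[s]][i]]]
      if (is.null(e$direct) || maskDraw[[s]][i]) {
        ZKin[i, kOff + seq_len(dKg)] <- e$recon
        useR[i] <- TRUE
      } else {
        ZKin[i, kOff + seq_len(dKg)] <- e$direct
      }
    }
    usedRecon[[s]] <- useR
  }
  ## fusion projections with dropout
  fus <- subParams(model$params, "fus", model$configs$fus)
  preS <- denseForward(ZSin, fus$W_S, fus$b_S)
  dpS <- dropoutForward(preS, cfg$fusionDropout, training)
  preK <- denseForward(ZKin, fus$W_SK, fus$b_SK)
  dpK <- dropoutForward(preK, cfg$fusionDropout, training)
  ## unstructured knowledge: the toy [CLS] row is the mean over content
  ## tokens, so rows vectorize into one grouped sum. Token ids per entity
  ## are cached (texts are frozen in the store).
  backbone <- modelBackbone(model)
  emb <- backbone$params$tok_embed
  entTokens <- function(kind, key) {
    tag <- paste0("tok.", kind, ".", key)
    ids <- get0(tag, envir = model$graphCache)
    if (is.null(ids)) {
      ids <- tokenizeText(ents[[kind]][[key]]$text, backbone)
      assign(tag, ids, envir = model$graphCache)
    }
    ids
  }
  budget <- 512L - 2L    # [CLS] and [SEP]
  contents <- vector("list", n)
  for (i in seq_len(n)) {
    a <- entTokens(sides[1], sideKeys[[1]][i])
    b <- if (length(sides) == 2L)
      entTokens(sides[2], sideKeys[[2]][i]) else integer()
    if (length(a) + length(b) > budget) {
      keepA <- floor(budget * length(a) / (length(a) + length(b)))
      keepB <- budget - keepA
      a <- head(a, keepA); b <- head(b, keepB)
    }
    contents[[i]] <- c(a, b)
  }
  lens <- lengths(contents)
  H1 <- matrix(0, n, cfg$dText)
  has <- which(lens > 0L)
  if (length(has)) {
    ids <- unlist(contents[has])
    H1[has, ] <- rowsumInto(emb[ids, , drop = FALSE],
                            rep(seq_along(has), lens[has]),
                            length(has)) / lens[has]
  }
  preU <- denseForward(H1, model$params$txt.W_UK, model$params$txt.b_UK)
  dpU <- dropoutForward(preU, cfg$textDropout, training)
  ## prediction head
  X <- cbind(dpS$Y, dpK$Y, dpU$Y)
  head <- subParams(model$params, "head", model$configs$head)
  mlp <- mlpForward(X, head)
  probs <- sigmoid(mlp$logits)
  keep <- !is.na(labels)
  loss <- bceLoss(probs[keep], labels[keep])
  list(loss = loss, probs = probs, labels = labels, keep = keep,
       ents = ents, kindFw = kindFw, saFwKind = saFwKind, uniq = uniq,
       sides = sides, sideKeys = sideKeys,
       maskDraw = maskDraw, usedRecon = usedRecon, ZSin = ZSin,
       ZKin = ZKin, dpS = dpS, dpK = dpK, dpU = dpU, H1 = H1,
       contents = contents, X = X, mlp = mlp, head = head, fus = fus,
       dStructs = dStructs, dKg = dKg, n = n)
}

batchBackward <- function(model, fw) {
  cfg <- model$config
  grads <- list()
  nKeep <- sum(fw$keep)
  dLogits <- matrix(0, nrow(fw$probs), ncol(fw$probs))
  dLogits[fw$keep] <- (fw$probs[fw$keep] - fw$labels[fw$keep]) / nKeep
  bkMlp <- mlpBackward(dLogits, fw$mlp, fw$head)
  for (nm in names(bkMlp$grads))
    grads[[paste0("head.", nm)]] <- bkMlp$grads[[nm]]
  dX <- bkMlp$dX
  dS <- cfg$dS; dK <- cfg$dSKOut; dU <- cfg$dUK
  dZS <- dropoutBackward(dX[, seq_len(dS), drop = FALSE], fw$dpS$mask)
  dZK <- dropoutBackward(dX[, dS + seq_len(dK), drop = FALSE],
                         fw$dpK$mask)
  dZU <- dropoutBackward(dX[, dS + dK + seq_len(dU), drop = FALSE],
                         fw$dpU$mask)
  bkS <- denseBackward(fw$ZSin, fw$fus$W_S, dZS)
  bkK <- denseBackward(fw$ZKin, fw$fus$W_SK, dZK)
  grads$fus.W_S <- bkS$dW;  grads$fus.b_S <- bkS$db
  grads$fus.W_SK <- bkK$dW; grads$fus.b_SK <- bkK$db
  bkU <- denseBackward(fw$H1, model$params$txt.W_UK, dZU)
  grads$txt.W_UK <- bkU$dW
  grads$txt.b_UK <- bkU$db
  ## token embeddings: [CLS] row of the toy backbone is the content mean
  nTok <- nrow(model$params$txt.tok_embed)
  dEmb <- matrix(0, nTok, cfg$dText)
  lens <- lengths(fw$contents)
  hasTok <- which(lens > 0L)
  if (length(hasTok)) {
    rows <- rep(hasTok, lens[hasTok])
    dEmb <- rowsumInto(bkU$dX[rows, , drop = FALSE] / lens[rows],
                       unlist(fw$contents[hasTok]), nTok)
  }
  grads$txt.tok_embed <- dEmb
  ## scatter structure/SK gradients back to unique biomolecules
  ents <- fw$ents
  dZkind <- list()
  dRecon <- list()
  for (s in seq_along(fw$sides)) {
    kind <- fw$sides[s]
    nU <- length(fw$uniq[[kind]])
    if (is.null(dZkind[[kind]]))
      dZkind[[kind]] <- matrix(0, nU, fw$dStructs[s])
    if (is.null(dRecon[[kind]]))
      dRecon[[kind]] <- matrix(0, nU, fw$dKg)
    sOff <- if (s == 1L) 0L else fw$dStructs[1]
    kOff <- (s - 1L) * fw$dKg
    rowsOf <- vapply(fw$sideKeys[[s]],
                     function(k) ents[[kind]][[k]]$row, 0L)
    dZkind[[kind]] <- dZkind[[kind]] +
      rowsumInto(bkS$dX[, sOff + seq_len(fw$dStructs[s]), drop = FALSE],
                 rowsOf, nU) / model$structScale[kind]
    if (cfg$reconstruct == "sparse" && any(fw$usedRecon[[s]])) {
      uR <- fw$usedRecon[[s]]
      dRecon[[kind]] <- dRecon[[kind]] +
        rowsumInto(bkK$dX[uR, kOff + seq_len(fw$dKg), drop = FALSE],
                   rowsOf[uR], nU)
    }
  }
  ## batched sparse-attention backward, then one batched encoder
  ## backward per kind
  for (kind in names(ents)) {
    saPre <- if (kind == "drug") "sa_d" else "sa_p"
    saFw <- fw$saFwKind[[kind]]
    if (!is.null(saFw)) {
      sa <- modelSaParams(model, kind)
      rowsU <- vapply(saFw$keys, function(k) ents[[kind]][[k]]$row, 0L)
      dZrec <- dRecon[[kind]][rowsU, , drop = FALSE]
      bkSa <- saBatchBackward(dZrec, saFw, sa)
      for (nm in names(bkSa$grads)) {
        full <- paste0(saPre, ".", nm)
        grads[[full]] <- (grads[[full]] %||% 0) + bkSa$grads[[nm]]
      }
      dZkind[[kind]][rowsU, ] <- dZkind[[kind]][rowsU, , drop = FALSE] +
        bkSa$dZstruct
    }
    encPre <- if (kind == "drug") "gin" else "mcnn"
    encParams <- subParams(model$params, encPre, model$configs[[encPre]])
    gEnc <- if (kind == "drug")
      encodeDrugsBackward(dZkind[[kind]], fw$kindFw[[kind]], encParams)
    else encodeProteinsBackward(dZkind[[kind]], fw$kindFw[[kind]],
                                encParams)
    for (nm in names(gEnc)) {
      full <- paste0(encPre, ".", nm)
      grads[[full]] <- (grads[[full]] %||% 0) + gEnc[[nm]]
    }
  }
  grads
}

tableRows <- function(tab, ids = NULL) {
  keys <- taskKeys(tab)
  lab <- taskLabels(tab)
  if (is.null(ids)) ids <- seq_along(tab)
  list(left = keys$left[ids],
       right = if (length(keys$right)) keys$right[ids] else NULL,
       labels = lab[ids, , drop = FALSE])
}

#' Train a model on a task table
#'
#' Minibatch Adam training (weight decay `1e-6` by default) with per-epoch
#' validation, best-epoch checkpointing and early stopping. Modality
#' masking is active with probability `config$maskP` during training and
#' disabled at evaluation. Fully reproducible given the config seed.
#'
#' @param model bundle from [modelInit()].
#' @param trainTab,validTab [TaskTable-class] objects (validTab may be
#'   `NULL` to skip validation and early stopping).
#' @param verbose print per-epoch progress.
#' @return the model with trained `params`, a `history` data.frame
#'   (epoch, train_loss, valid_metric) and `bestEpoch`.
#' @export
trainModel <- function(model, trainTab, validTab = NULL,
                       verbose = FALSE) {
  cfg <- model$config
  if (length(trainTab) == 0L) stop("training table is empty")
  set.seed(deriveSeed(cfg$seed, "train"))
  opt <- adamInit(model$params, lr = cfg$lr,
                  weightDecay = cfg$weightDecay)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_metric = numeric())
  best <- -Inf
  bestParams <- model$params
  bestEpoch <- 0L
  wait <- 0L
  nTrain <- length(trainTab)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(nTrain)
    losses <- numeric()
    for (start in seq(1L, nTrain, by = cfg$batchSize)) {
      ids <- ord[start:min(start + cfg$batchSize - 1L, nTrain)]
      rows <- tableRows(trainTab, ids)
      fw <- batchForward(model, rows$left, rows$right, rows$labels,
                         training = TRUE)
      grads <- batchBackward(model, fw)
      clip <- cfg$clipNorm %||% Inf
      if (is.finite(clip)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
        if (gn > clip)
          grads <- lapply(grads, function(g) g * (clip / gn))
      }
      if (cfg$lr > 0) {
        step <- adamStep(model$params, grads, opt)
        model$params <- step$params
        opt <- step$state
      }
      losses <- c(losses, fw$loss)
    }
    vm <- NA_real_
    if (!is.null(validTab) && length(validTab) > 0L) {
      ev <- evaluateModel(model, validTab)
      vm <- if (model$task == "PPI") ev@microF1 else ev@auroc
      if (!is.na(vm) && vm > best) {
        best <- vm
        bestParams <- model$params
        bestEpoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = mean(losses),
                                valid_metric = vm))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f valid %.4f", epoch,
                      mean(losses), vm))
    if (!is.null(validTab) && wait >= cfg$patience) break
  }
  if (!is.null(validTab) && bestEpoch > 0L) model$params <- bestParams
  model$history <- history
  model$bestEpoch <- if (bestEpoch > 0L) bestEpoch else nrow(history)
  model$bestMetric <- if (is.finite(best)) best else NA_real_
  model
}

#' Predict probabilities for every row of a task table
#'
#' Evaluation mode: dropout off, modality masking off, no RNG use.
#'
#' @param model trained model bundle.
#' @param tab a [TaskTable-class].
#' @return numeric matrix of probabilities (rows x nLabels).
#' @export
predictTable <- function(model, tab) {
  rows <- tableRows(tab)
  out <- matrix(NA_real_, length(tab), model$nLabels)
  bs <- model$config$batchSize
  for (start in seq(1L, length(tab), by = bs)) {
    ids <- start:min(start + bs - 1L, length(tab))
    fw <- batchForward(model, rows$left[ids],
                       if (!is.null(rows$right)) rows$right[ids],
                       rows$labels[ids, , drop = FALSE],
                       training = FALSE)
    out[ids, ] <- fw$probs
  }
  out
}

#' MetricReport: evaluation metrics with per-fold detail
#'
#' @slot auroc,aupr,microF1 pooled metric values in [0, 1] (NA when
#'   undefined for the task).
#' @slot perFold data.frame of per-fold values (empty for single splits).
#' @exportClass MetricReport
setClass("MetricReport",
  representation(auroc = "numeric", aupr = "numeric",
                 microF1 = "numeric", perFold = "data.frame"))

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: auroc %.4f aupr %.4f microF1 %.4f\n",
              object@auroc, object@aupr, object@microF1))
  if (nrow(object@perFold)) {
    m <- colMeans(object@perFold, na.rm = TRUE)
    s <- apply(object@perFold, 2, sd)
    cat("  per-fold mean +/- sd over", nrow(object@perFold), "folds:\n")
    for (nm in names(m))
      cat(sprintf("    %s: %.4f +/- %.4f\n", nm, m[nm], s[nm]))
  }
})

#' Evaluate a model on a task table
#'
#' @param model trained model bundle.
#' @param tab a [TaskTable-class].
#' @param threshold decision threshold for micro-F1 (default 0.5).
#' @return a [MetricReport-class].
#' @export
evaluateModel <- function(model, tab, threshold = 0.5) {
  probs <- predictTable(model, tab)
  lab <- taskLabels(tab)
  keep <- !is.na(lab)
  sc <- probs[keep]
  y <- lab[keep]
  au <- if (length(unique(y)) == 2L) auroc(sc, y) else NA_real_
  ap <- if (length(unique(y)) == 2L) aupr(sc, y) else NA_real_
  f1 <- microF1(probs, lab, threshold = threshold)
  new("MetricReport", auroc = au, aupr = ap, microF1 = f1,
      perFold = data.frame())
}

#' Sample negative pairs for a positives-only interaction table
#'
#' Uniformly samples unordered non-positive pairs at the requested ratio,
#' excluding every known positive, and returns the augmented table.
#'
#' @param tab a [TaskTable-class] with all-positive labels (pair tasks).
#' @param ratio negatives per positive (default 1).
#' @param seed RNG seed.
#' @return a [TaskTable-class] with sampled negatives appended.
#' @export
sampleNegativePairs <- function(tab, ratio = 1, seed = 1L) {
  task <- taskName(tab)
  if (task == "DP") stop("negative sampling applies to pair tasks only")
  keys <- taskKeys(tab)
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  known <- unique(pairKey(keys$left, keys$right))
  lefts <- unique(keys$left)
  rights <- unique(keys$right)
  nNeg <- ceiling(ratio * length(tab))
  set.seed(seed)
  out <- character(0); outL <- character(0); outR <- character(0)
  guard <- 0L
  while (length(outL) < nNeg && guard < 50L) {
    m <- nNeg * 2L
    cl <- sample(lefts, m, replace = TRUE)
    cr <- sample(rights, m, replace = TRUE)
    ok <- cl != cr & !(pairKey(cl, cr) %in% known) &
      !(pairKey(cl, cr) %in% out)
    add <- which(ok)[!duplicated(pairKey(cl, cr)[ok])]
    outL <- c(outL, cl[add]); outR <- c(outR, cr[add])
    out <- c(out, pairKey(cl, cr)[add])
    guard <- guard + 1L
  }
  if (length(outL) > nNeg) {
    outL <- outL[seq_len(nNeg)]; outR <- outR[seq_len(nNeg)]
  }
  lab <- taskLabels(tab)
  taskTable(task, c(keys$left, outL), c(keys$right, outR),
            rbind(lab, matrix(0, length(outL), ncol(lab))))
}
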