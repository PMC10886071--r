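## Synthetic multimodal corpus with planted, recoverable signal.
##
## Entities (drugs + proteins) are assigned to B communities. The
## knowledge graph is a stochastic block model (within-community edge
## probability pIn, across pOut). Community membership is mirrored in the
## structures (community-specific SMILES ring backbone; community 4-mer
## sequence motif) and in the templated texts. A second, community-
## independent binary trait ("motif id") is planted purely structurally
## (marker heteroatom in drugs; a dedicated 4-mer in proteins) and in the
## texts. Default task labels are an XOR of community match and motif
## match, so neither the knowledge-graph channel nor the structure channel
## suffices alone -- ablating either measurably degrades performance.

drugBackbones <- c("C1CCCCC1", "c1ccccc1", "C1CCCC1", "C1CC1",
                   "C1CCCCCC1", "C1COCC1", "C1CCNCC1", "C1CCSCC1")
communityMotifs <- c("HHHH", "KKKK", "RRRR", "DDDD",
                     "EEEE", "QQQQ", "NNNN", "TTTT")
bitMotifs <- c("FPFP", "WYWY")     # motif id 0 / 1
bitMarkers <- c("O", "N")          # drug marker atom for motif id 0 / 1

## Enumerate candidate SMILES for one (community, motif-bit) cell.
drugTemplates <- function(community, bit) {
  chains <- c("", "C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
  branches <- c("", "C(C)")
  core <- drugBackbones[community]
  marker <- bitMarkers[bit + 1L]
  grid <- expand.grid(c1 = chains, br = branches, c2 = chains,
                      stringsAsFactors = FALSE)
  paste0(core, grid$c1, grid$br, marker, grid$c2)
}

randomProtein <- function(len, community, bit, plantCommunity = TRUE) {
  aas <- setdiff(aminoAcidAlphabet(), "X")
  body <- paste(sample(aas, len, replace = TRUE), collapse = "")
  bm <- bitMotifs[bit + 1L]
  ## overwrite two non-overlapping 4-mer windows
  p1 <- sample(seq_len(len - 8L), 1L)
  p2 <- sample(setdiff(seq_len(len - 3L),
                       (p1 - 3L):(p1 + 3L)), 1L)
  if (plantCommunity)
    substr(body, p1, p1 + 3L) <- communityMotifs[community]
  substr(body, p2, p2 + 3L) <- bm
  body
}

entityText <- function(id, community, bit) {
  paste0("Entity ", id, " belongs to family F", community,
         " and carries structural motif M", bit, ".")
}

#' Generate a synthetic multimodal corpus
#'
#' Deterministic given `seed`. Knowledge-graph edges follow a stochastic
#' block model over all entities; drug SMILES come from per-community
#' template sets (community ring backbone, motif-bit marker heteroatom,
#' varying alkyl decorations); protein sequences are random over the 20
#' standard residues with a planted community 4-mer and a motif-bit 4-mer;
#' texts are templated from the ground truth. A fraction `fMiss` of
#' entities is withheld from the store indices (their structured and
#' unstructured knowledge is missing at resolution time); the withheld set
#' is uniform over communities (a chi-square sanity p-value is recorded in
#' `params`).
#'
#' @param nDrugs,nProteins entity counts (defaults 200 and 100).
#' @param B number of communities (default 4, at most 8).
#' @param pIn,pOut within/across-community edge probabilities (defaults
#'   0.2 and 0.01; `pIn > pOut` required).
#' @param fMiss fraction of entities withheld from the store (default 0).
#' @param structAssoc probability that an entity's structure reflects its
#'   community (default 0.7): with the complementary probability a drug
#'   draws its backbone from another community's template set and a
#'   protein carries no community motif. Keeping this association partial
#'   makes the knowledge-graph channel genuinely necessary: structure
#'   alone cannot fully recover community membership, while the motif bit
#'   stays purely structural.
#' @param seed RNG seed.
#' @return a [SyntheticCorpus-class].
#' @export
generateCorpus <- function(nDrugs = 200L, nProteins = 100L, B = 4L,
                           pIn = 0.2, pOut = 0.01, fMiss = 0,
                           structAssoc = 0.7, seed = 1L) {
  if (!(pIn > pOut)) stop("pIn must exceed pOut")
  if (fMiss < 0 || fMiss >= 1) stop("fMiss must be in [0, 1)")
  if (structAssoc < 0 || structAssoc > 1)
    stop("structAssoc must be in [0, 1]")
  if (B < 1L || B > length(drugBackbones))
    stop("B must be between 1 and ", length(drugBackbones))
  set.seed(deriveSeed(seed, "corpus"))
  nEnt <- nDrugs + nProteins
  ids <- c(sprintf("D%03d", seq_len(nDrugs)),
           sprintf("P%03d", seq_len(nProteins)))
  kind <- rep(c("drug", "protein"), c(nDrugs, nProteins))
  community <- c(sample(rep(seq_len(B), length.out = nDrugs)),
                 sample(rep(seq_len(B), length.out = nProteins)))
  bit <- rbinom(nEnt, 1L, 0.5)
  ## which entities express their community structurally
  expresses <- runif(nEnt) < structAssoc
  ## drugs: sample distinct templates from the (backbone community, bit)
  ## cells; non-expressing drugs draw from a random other community
  bcOf <- community[kind == "drug"]
  flip <- which(!expresses[kind == "drug"])
  if (B > 1L) for (i in flip)
    bcOf[i] <- sample(setdiff(seq_len(B), bcOf[i]), 1L)
  drugSmiles <- character(nDrugs)
  mD <- bit[kind == "drug"]
  for (b in seq_len(B)) for (m in 0:1) {
    cell <- which(bcOf == b & mD == m)
    if (!length(cell)) next
    cand <- drugTemplates(b, m)
    if (length(cell) > length(cand))
      stop("not enough drug templates for community ", b, " bit ", m)
    drugSmiles[cell] <- sample(cand, length(cell))
  }
  drugs <- lapply(drugSmiles, parseMolecule)
  dKeys <- vapply(drugs, canonicalKey, "")
  if (anyDuplicated(dKeys))
    stop("drug template collision after canonicalization")
  names(drugs) <- ids[kind == "drug"]
  ## proteins
  lens <- sample(30:45, nProteins, replace = TRUE)
  pidx <- which(kind == "protein")
  proteins <- lapply(seq_len(nProteins), function(j)
    proteinSequence(ids[pidx[j]],
                    randomProtein(lens[j], community[pidx[j]],
                                  bit[pidx[j]],
                                  plantCommunity = expresses[pidx[j]])))
  pKeys <- vapply(proteins, canonicalKey, "")
  names(proteins) <- ids[pidx]
  keys <- character(nEnt)
  keys[kind == "drug"] <- dKeys
  keys[pidx] <- pKeys
  ## stochastic block model knowledge graph
  pr <- utils::combn(nEnt, 2L)
  same <- community[pr[1, ]] == community[pr[2, ]]
  p <- ifelse(same, pIn, pOut)
  edge <- runif(ncol(pr)) < p
  kb <- knowledgeBase(h = ids[pr[1, edge]],
                      r = ifelse(same[edge], "intra_family_link",
                                 "cross_family_link"),
                      t = ids[pr[2, edge]],
                      entities = ids)
  ## store with fMiss withheld entities
  nMiss <- floor(fMiss * nEnt)
  withheld <- if (nMiss > 0L) sort(sample(nEnt, nMiss)) else integer()
  present <- setdiff(seq_len(nEnt), withheld)
  chisqP <- NA_real_
  if (nMiss >= B) {
    tab <- table(factor(community[withheld], levels = seq_len(B)))
    chisqP <- suppressWarnings(chisq.test(tab)$p.value)
  }
  texts <- structure(
    vapply(present, function(i)
      entityText(ids[i], community[i], bit[i]), ""),
    names = ids[present])
  pd <- present[kind[present] == "drug"]
  pp <- present[kind[present] == "protein"]
  store <- knowledgeStore(
    kb,
    drugIndex = structure(ids[pd], names = keys[pd]),
    proteinIndex = structure(ids[pp], names = keys[pp]),
    texts = texts)
  gt <- data.frame(entity_id = ids, kind = kind, community = community,
                   motif = bit, key = keys, stringsAsFactors = FALSE)
  new("SyntheticCorpus", store = store, drugs = drugs,
      proteins = proteins, groundTruth = gt,
      params = list(nDrugs = nDrugs, nProteins = nProteins, B = B,
                    pIn = pIn, pOut = pOut, fMiss = fMiss,
                    structAssoc = structAssoc, seed = seed,
                    withheld = ids[withheld], chisqP = chisqP))
}

## Evaluate a label rule on ground-truth attributes.
labelRule <- function(rule, cL, mL, cR = NULL, mR = NULL) {
  switch(rule,
    community_xor_motif = as.numeric(xor(cL == cR, mL == mR)),
    same_community = as.numeric(cL == cR),
    community_parity = as.numeric(cL %% 2L == 1L),
    stop("unknown label rule: ", rule))
}

#' Generate a labeled task dataset from a synthetic corpus
#'
#' Labels are an exact function of the planted ground truth. The default
#' pair rule is `community_xor_motif`: label 1 iff (same community) XOR
#' (same motif id) -- solvable only by combining the knowledge-graph and
#' structure channels. The default DP rule is `community_parity`. For PPI
#' the pair rules are stacked into a 3-type multi-label target
#' (same family, same motif, their XOR). When `nRows` exceeds the number
#' of available rows it is capped with a warning.
#'
#' @param corpus a [SyntheticCorpus-class].
#' @param task task tag.
#' @param rule label rule (`"community_xor_motif"`, `"same_community"`,
#'   `"community_parity"`); ignored for PPI which uses the stacked rule.
#' @param nRows number of rows to sample (without replacement).
#' @param seed RNG seed.
#' @return a [TaskTable-class] keyed by canonical structure keys, with a
#'   `"classBalance"` attribute.
#' @export
generateTaskDataset <- function(corpus, task = c("DTI", "DP", "DDI",
                                                 "PPI"),
                                rule = NULL, nRows = 1000L, seed = 1L) {
  task <- match.arg(task)
  gt <- groundTruth(corpus)
  set.seed(deriveSeed(seed, paste0("task", task)))
  dr <- gt[gt$kind == "drug", ]
  pt <- gt[gt$kind == "protein", ]
  if (task == "DP") {
    rule <- rule %||% "community_parity"
    if (nRows > nrow(dr)) {
      warning("nRows capped at the number of drugs (", nrow(dr), ")")
      nRows <- nrow(dr)
    }
    pick <- sort(sample(nrow(dr), nRows))
    lab <- labelRule(rule, dr$community[pick], dr$motif[pick])
    tab <- taskTable("DP", dr$key[pick], labels = lab)
    attr(tab, "classBalance") <- mean(lab)
    return(tab)
  }
  sidesDf <- switch(task,
    DTI = list(L = dr, R = pt),
    DDI = list(L = dr, R = dr),
    PPI = list(L = pt, R = pt))
  if (task == "DTI") {
    pairs <- as.matrix(expand.grid(i = seq_len(nrow(dr)),
                                   j = seq_len(nrow(pt))))
  } else {
    pairs <- t(utils::combn(nrow(sidesDf$L), 2L))
    colnames(pairs) <- c("i", "j")
  }
  if (nRows > nrow(pairs)) {
    warning("nRows capped at the number of available pairs (",
            nrow(pairs), ")")
    nRows <- nrow(pairs)
  }
  pick <- pairs[sample(nrow(pairs), nRows), , drop = FALSE]
  L <- sidesDf$L[pick[, "i"], ]
  R <- sidesDf$R[pick[, "j"], ]
  if (task == "PPI") {
    lab <- cbind(
      label_same_family = labelRule("same_community", L$community,
                                    L$motif, R$community, R$motif),
      label_same_motif = as.numeric(L$motif == R$motif),
      label_xor = labelRule("community_xor_motif", L$community, L$motif,
                            R$community, R$motif))
    tab <- taskTable("PPI", L$key, R$key, lab)
  } else {
    rule <- rule %||% "community_xor_motif"
    lab <- labelRule(rule, L$community, L$motif, R$community, R$motif)
    tab <- taskTable(task, L$key, R$key, lab)
  }
  attr(tab, "classBalance") <- mean(taskLabels(tab), na.rm = TRUE)
  tab
}

#' Write a synthetic corpus to a directory
#'
#' The store is written in the [writeKnowledgeStore()] layout plus
#' `ground_truth.json` and `params.json`, so downstream commands consume
#' synthetic and real corpora identically.
#'
#' @param corpus a [SyntheticCorpus-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  writeKnowledgeStore(corpusStore(corpus), dir)
  jsonlite::write_json(groundTruth(corpus),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(corpus@params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a synthetic corpus written by [writeCorpus()]
#'
#' @param dir directory path.
#' @return a [SyntheticCorpus-class].
#' @export
readCorpus <- function(dir) {
  store <- readKnowledgeStore(dir)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  params <- as.list(jsonlite::fromJSON(file.path(dir, "params.json")))
  dkeys <- gt$key[gt$kind == "drug"]
  drugs <- lapply(dkeys, parseMolecule)
  names(drugs) <- gt$entity_id[gt$kind == "drug"]
  pids <- gt$entity_id[gt$kind == "protein"]
  proteins <- lapply(seq_along(pids), function(j)
    proteinSequence(pids[j], gt$key[gt$kind == "protein"][j]))
  names(proteins) <- pids
  new("SyntheticCorpus", store = store, drugs = drugs,
      proteins = proteins, groundTruth = gt, params = params)
}
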