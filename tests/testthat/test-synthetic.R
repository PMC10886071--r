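test_that("corpus generation is reproducible and parses everywhere", {
  c1 <- generateCorpus(nDrugs = 20, nProteins = 12, B = 2, pIn = 0.4,
                       pOut = 0.05, seed = 9)
  c2 <- generateCorpus(nDrugs = 20, nProteins = 12, B = 2, pIn = 0.4,
                       pOut = 0.05, seed = 9)
  expect_identical(groundTruth(c1), groundTruth(c2))
  expect_identical(triplets(storeKb(corpusStore(c1))),
                   triplets(storeKb(corpusStore(c2))))
  ## every drug parses and is keyed by its canonical SMILES
  for (g in c1@drugs) expect_s4_class(g, "MolecularGraph")
  keys <- vapply(c1@drugs, canonicalKey, "")
  expect_false(anyDuplicated(keys) > 0)
  ## parameter contract errors
  expect_error(generateCorpus(pIn = 0.1, pOut = 0.2), "pIn")
  expect_error(generateCorpus(fMiss = 1), "fMiss")
  expect_error(generateCorpus(B = 99), "B must be")
})

test_that("fMiss withholds entities uniformly; zero means all resolvable", {
  c0 <- generateCorpus(nDrugs = 20, nProteins = 12, B = 2, pIn = 0.4,
                       pOut = 0.05, fMiss = 0, seed = 3)
  st <- corpusStore(c0)
  gt <- groundTruth(c0)
  for (i in seq_len(nrow(gt))) {
    kind <- gt$kind[i]
    expect_false(isStoreMiss(storeLookup(st, gt$key[i], kind)))
  }
  cM <- generateCorpus(nDrugs = 40, nProteins = 24, B = 4, pIn = 0.3,
                       pOut = 0.02, fMiss = 0.5, seed = 3)
  expect_equal(length(cM@params$withheld), 32L)
  expect_false(is.na(cM@params$chisqP))
  ## withheld entities actually miss
  wid <- cM@params$withheld[1]
  gtM <- groundTruth(cM)
  row <- gtM[gtM$entity_id == wid, ]
  expect_true(isStoreMiss(storeLookup(corpusStore(cM), row$key,
                                      row$kind)))
})

test_that("p_out = 0 with B = 2 gives components aligned with communities", {
  c0 <- generateCorpus(nDrugs = 20, nProteins = 12, B = 2, pIn = 0.5,
                       pOut = 0, seed = 5)
  A <- buildAdjacency(storeKb(corpusStore(c0)))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  expect_gte(comp$no, 2L)
  gt <- groundTruth(c0)
  ## each non-singleton component is community-pure
  memb <- comp$membership[gt$entity_id]
  for (cc in unique(memb)) {
    inC <- gt$community[memb == cc]
    if (length(inC) > 1L) expect_length(unique(inC), 1L)
  }
})

test_that("KG communities are recoverable by spectral clustering", {
  corpus <- generateCorpus(nDrugs = 200, nProteins = 100, B = 4,
                           pIn = 0.2, pOut = 0.01, seed = 21)
  gt <- groundTruth(corpus)
  emb <- embeddingMatrix(kgEmbed(storeKb(corpusStore(corpus)),
                                 dKg = 16, seed = 2))
  set.seed(4)
  km <- stats::kmeans(emb, centers = 4, nstart = 10)
  ## adjusted agreement via best cluster-to-community matching
  tab <- table(km$cluster, gt$community)
  agree <- sum(apply(tab, 1, max)) / nrow(gt)
  expect_gte(agree, 0.9)
  ## within-community embeddings are closer than across
  Hn <- emb / sqrt(rowSums(emb^2) + 1e-12)
  S <- Hn %*% t(Hn); diag(S) <- NA
  same <- outer(gt$community, gt$community, "==")
  expect_gt(mean(S[same], na.rm = TRUE), mean(S[!same], na.rm = TRUE))
})

test_that("task labels equal a direct re-evaluation of the rule", {
  corpus <- sharedCorpus()
  gt <- groundTruth(corpus)
  rownames(gt) <- gt$key
  tab <- generateTaskDataset(corpus, "DTI", nRows = 150, seed = 8)
  keys <- taskKeys(tab)
  lab <- taskLabels(tab)[, 1]
  for (i in seq_along(lab)) {
    L <- gt[keys$left[i], ]; R <- gt[keys$right[i], ]
    expect_equal(lab[i],
                 as.numeric(xor(L$community == R$community,
                                L$motif == R$motif)))
  }
  ## balance within the documented band for the default rule
  big <- generateTaskDataset(corpus, "DTI", nRows = 600, seed = 8)
  expect_gte(attr(big, "classBalance"), 0.4)
  expect_lte(attr(big, "classBalance"), 0.6)
  ## determinism
  tab2 <- generateTaskDataset(corpus, "DTI", nRows = 150, seed = 8)
  expect_identical(taskKeys(tab2), taskKeys(tab))
  ## same_community rule on a within-community pair
  sc <- generateTaskDataset(corpus, "DTI", rule = "same_community",
                            nRows = 150, seed = 2)
  lab2 <- taskLabels(sc)[, 1]
  k2 <- taskKeys(sc)
  i <- which(gt[k2$left, "community"] == gt[k2$right, "community"])[1]
  expect_equal(lab2[i], 1)
  ## oversized requests are capped with a warning
  expect_warning(generateTaskDataset(corpus, "DP", nRows = 1e6),
                 "capped")
  expect_error(generateTaskDataset(corpus, "DTI", rule = "nope",
                                   nRows = 10), "unknown label rule")
})

test_that("corpus serialization round-trips through the store layout", {
  corpus <- generateCorpus(nDrugs = 12, nProteins = 8, B = 2, pIn = 0.4,
                           pOut = 0.05, fMiss = 0.25, seed = 13)
  d <- tempfile()
  writeCorpus(corpus, d)
  expect_true(all(file.exists(file.path(d, c("kb.tsv", "drugs.tsv",
                                             "proteins.tsv",
                                             "texts.jsonl",
                                             "ground_truth.json")))))
  back <- readCorpus(d)
  expect_identical(groundTruth(back)$entity_id,
                   groundTruth(corpus)$entity_id)
  expect_identical(groundTruth(back)$community,
                   groundTruth(corpus)$community)
  expect_identical(back@store@drugIndex, corpus@store@drugIndex)
  expect_identical(sort(names(back@store@texts)),
                   sort(names(corpus@store@texts)))
})
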