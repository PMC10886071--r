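test_that("store lookup is exact-match on canonical keys", {
  kb <- knowledgeBase(c("d1", "p1"), c("binds", "r"), c("p1", "p2"))
  key1 <- canonicalSmiles("CCO")
  store <- knowledgeStore(kb,
                          drugIndex = structure("d1", names = key1),
                          proteinIndex = structure("p1", names = "MKV"),
                          texts = c(d1 = "ethanol-like compound"))
  expect_identical(storeLookup(store, key1, "drug"), "d1")
  expect_true(isStoreMiss(storeLookup(store, "CCC", "drug")))
  ## chemically identical spellings resolve to the same entity
  expect_identical(storeLookup(store, canonicalSmiles("OCC"), "drug"),
                   "d1")
  expect_identical(storeLookup(store, "MKV", "protein"), "p1")
})

test_that("knowledge store serialization round-trips", {
  corpus <- sharedCorpus()
  store <- corpusStore(corpus)
  d <- tempfile()
  writeKnowledgeStore(store, d)
  store2 <- readKnowledgeStore(d)
  expect_identical(entities(storeKb(store2)), entities(storeKb(store)))
  expect_identical(sort(triplets(storeKb(store2))$h),
                   sort(triplets(storeKb(store))$h))
  expect_identical(store2@drugIndex, store@drugIndex)
  expect_identical(store2@proteinIndex, store@proteinIndex)
  expect_identical(sort(names(store2@texts)), sort(names(store@texts)))
})

test_that("sparse attention matches the brute-force top-k oracle", {
  set.seed(101)
  nE <- 64; dKg <- 16
  H <- matrix(rnorm(nE * dKg), nE, dKg)
  for (nHeads in c(1L, 4L)) {
    for (k in c(1L, 4L, 16L, 64L)) {
      params <- sparseAttentionParams(8L, dKg, nHeads = nHeads, k = k,
                                      seed = k + nHeads)
      for (trial in 1:12) {
        z <- rnorm(8)
        got <- as.numeric(sparseAttentionReconstruct(z, H, params))
        ref <- sparseAttentionOracle(z, H, params)
        expect_lt(max(abs(got - ref)), 1e-6)
      }
    }
  }
})

test_that("sparse attention equals dense attention when k >= |E|", {
  set.seed(103)
  nE <- 32; dKg <- 8
  H <- matrix(rnorm(nE * dKg), nE, dKg)
  params <- sparseAttentionParams(6L, dKg, nHeads = 2L, k = nE, seed = 5)
  for (trial in 1:50) {
    z <- rnorm(6)
    got <- as.numeric(sparseAttentionReconstruct(z, H, params))
    ref <- denseAttentionOracle(z, H, params)
    expect_lt(max(abs(got - ref)), 1e-9)
  }
})

test_that("attention weights are a sparse convex combination", {
  set.seed(107)
  nE <- 40; dKg <- 12
  H <- matrix(rnorm(nE * dKg), nE, dKg)
  params <- sparseAttentionParams(5L, dKg, nHeads = 3L, k = 7L, seed = 9)
  z <- rnorm(5)
  out <- sparseAttentionReconstruct(z, H, params)
  at <- attr(out, "attention")
  expect_length(at, 3L)
  for (h in seq_along(at)) {
    w <- at[[h]]$w
    expect_lte(length(w), 7L)
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-9)
    ## the head output is reproduced by the stated convex combination of
    ## the selected knowledge-graph rows
    cols <- at[[h]]$cols
    rebuilt <- drop(crossprod(H[at[[h]]$sel, cols, drop = FALSE], w))
    expect_lt(max(abs(rebuilt - as.numeric(out)[cols])), 1e-12)
  }
})

test_that("single head with k = 1 returns exactly one embedding row", {
  set.seed(109)
  H <- matrix(rnorm(10 * 6), 10, 6)
  params <- sparseAttentionParams(4L, 6L, nHeads = 1L, k = 1L, seed = 3)
  z <- rnorm(4)
  out <- as.numeric(sparseAttentionReconstruct(z, H, params))
  sel <- attr(sparseAttentionReconstruct(z, H, params),
              "attention")[[1]]$sel
  expect_equal(out, H[sel, ], tolerance = 1e-12)
})

test_that("top-k ties keep the lowest entity row index", {
  ## identical rows produce identical scores; the selection must be the
  ## first k row indices
  H <- matrix(1, 6, 4)
  params <- sparseAttentionParams(3L, 4L, nHeads = 1L, k = 3L, seed = 1)
  out <- sparseAttentionReconstruct(c(1, 2, 3), H, params)
  expect_identical(attr(out, "attention")[[1]]$sel, 1:3)
})

test_that("sparse attention contract errors", {
  H <- matrix(rnorm(8), 2, 4)
  expect_error(sparseAttentionParams(3L, 4L, nHeads = 1L, k = 0L),
               "k must be")
  expect_error(sparseAttentionParams(3L, 6L, nHeads = 4L), "divisible")
  params <- sparseAttentionParams(3L, 4L, nHeads = 1L, k = 2L)
  expect_error(sparseAttentionReconstruct(c(1, 2, 3),
                                          matrix(0, 0, 4), params),
               "at least one row")
  expect_error(sparseAttentionReconstruct(c(1, 2), H, params), "width")
})

test_that("modality masking has the right rates and is a no-op off-path", {
  kb <- toyKb()
  emb <- kgEmbed(kb, dKg = 2, seed = 1)
  rec <- new("MultimodalRecord", kind = "drug", key = "k",
             entityId = "d1", zSK = lookupEmbedding(emb, "d1"),
             skProvenance = "direct", text = "t", textPresent = TRUE)
  ## P = 0 never masks (the evaluation setting)
  set.seed(1)
  for (i in 1:50)
    expect_identical(applyModalityMasking(rec, 0)@skProvenance, "direct")
  ## P = 1 always masks
  expect_identical(applyModalityMasking(rec, 1)@skProvenance,
                   "masked_reconstructed")
  ## masking a non-direct record is a no-op
  recR <- rec; recR@skProvenance <- "reconstructed"
  expect_identical(applyModalityMasking(recR, 1)@skProvenance,
                   "reconstructed")
  expect_error(applyModalityMasking(rec, 1.5), "\\[0, 1\\]")

  ## binomial band at P = 0.05 over 20000 draws (central 99.7% interval)
  set.seed(77)
  masked <- vapply(seq_len(20000), function(i)
    applyModalityMasking(rec, 0.05)@skProvenance ==
      "masked_reconstructed", TRUE)
  frac <- mean(masked)
  expect_gte(frac, 0.0454)
  expect_lte(frac, 0.0546)
})

test_that("resolveRecord picks the right branch and provenance", {
  corpus <- sharedCorpus()
  store <- corpusStore(corpus)
  kb <- storeKb(store)
  emb <- kgEmbed(kb, dKg = 8, seed = 3)
  sa <- sparseAttentionParams(4L, 8L, nHeads = 2L, k = 4L, seed = 5)
  z <- rnorm(4)
  knownKey <- names(store@drugIndex)[1]
  ## known drug, evaluation: direct, stored text
  r1 <- resolveRecord(store, emb, sa, knownKey, "drug", z,
                      training = FALSE, P = 0)
  expect_identical(r1@skProvenance, "direct")
  expect_true(r1@textPresent)
  expect_identical(r1@zSK,
                   lookupEmbedding(emb, storeLookup(store, knownKey,
                                                    "drug")))
  ## unknown drug: reconstructed, empty text
  r2 <- resolveRecord(store, emb, sa, "CCCCCCCCCC", "drug", z)
  expect_identical(r2@skProvenance, "reconstructed")
  expect_false(r2@textPresent)
  expect_identical(r2@text, "")
  expect_equal(r2@zSK, as.numeric(sparseAttentionReconstruct(z, emb, sa)))
  ## known drug, training with P = 1: forced masked reconstruction that
  ## differs from the direct row
  set.seed(11)
  r3 <- resolveRecord(store, emb, sa, knownKey, "drug", z,
                      training = TRUE, P = 1)
  expect_identical(r3@skProvenance, "masked_reconstructed")
  expect_false(isTRUE(all.equal(r3@zSK, r1@zSK)))
  ## evaluation mode is rng-independent
  set.seed(1); a <- resolveRecord(store, emb, sa, knownKey, "drug", z)
  set.seed(999); b <- resolveRecord(store, emb, sa, knownKey, "drug", z)
  expect_identical(a@zSK, b@zSK)
})
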