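mkRows <- function(nDrug = 12, nProt = 8, n = 120, seed = 5) {
  set.seed(seed)
  drugs <- paste0("drug", seq_len(nDrug))
  prots <- paste0("prot", seq_len(nProt))
  list(left = sample(drugs, n, replace = TRUE),
       right = sample(prots, n, replace = TRUE))
}

test_that("warm split partitions rows into disjoint exhaustive folds", {
  rows <- mkRows()
  sp <- makeInteractionSplit(rows, "warm", nFolds = 5, seed = 2)
  tests <- lapply(folds(sp), `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_along(rows$left))
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(tests[[i]], tests[[j]]), 0L)
  for (f in folds(sp)) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$train, f$valid), 0L)
  }
})

test_that("cold splits keep held-out entities unseen in training", {
  rows <- mkRows()
  spD <- makeInteractionSplit(rows, "cold_drug", nFolds = 4, seed = 3)
  for (f in folds(spD))
    expect_length(intersect(rows$left[f$train], rows$left[f$test]), 0L)
  spP <- makeInteractionSplit(rows, "cold_protein", nFolds = 4, seed = 3)
  for (f in folds(spP))
    expect_length(intersect(rows$right[f$train], rows$right[f$test]), 0L)
  ## contract: more folds than entities
  expect_error(makeInteractionSplit(list(left = c("a", "b"),
                                         right = c("x", "y")),
                                    "cold_drug", nFolds = 5),
               "fewer distinct")
})

test_that("cold_cluster yields 9 folds with both entities unseen", {
  rows <- mkRows(nDrug = 15, nProt = 9, n = 200)
  sp <- makeInteractionSplit(rows, "cold_cluster", seed = 7)
  expect_length(folds(sp), 9L)
  for (f in folds(sp)) {
    expect_length(intersect(rows$left[f$train], rows$left[f$test]), 0L)
    expect_length(intersect(rows$right[f$train], rows$right[f$test]), 0L)
  }
})

test_that("splits are deterministic per seed and row-order invariant", {
  rows <- mkRows()
  s1 <- makeInteractionSplit(rows, "cold_drug", nFolds = 3, seed = 11)
  s2 <- makeInteractionSplit(rows, "cold_drug", nFolds = 3, seed = 11)
  expect_identical(folds(s1), folds(s2))
  ## permuting rows permutes ids but holds the entity partition fixed
  perm <- sample(seq_along(rows$left))
  rowsP <- list(left = rows$left[perm], right = rows$right[perm])
  s3 <- makeInteractionSplit(rowsP, "cold_drug", nFolds = 3, seed = 11)
  for (k in 1:3)
    expect_setequal(unique(rowsP$left[folds(s3)[[k]]$test]),
                    unique(rows$left[folds(s1)[[k]]$test]))
})

test_that("scaffold split never places one scaffold in two partitions", {
  smiles <- c("c1ccccc1CC", "c1ccccc1CCC", "c1ccccc1CCCC",
              "C1CCCCC1N", "C1CCCCC1NC", "C1CCNCC1C",
              "C1CCSCC1C", "C1CC1CC", "C1COCC1C", "CCO", "CCC", "CCCC")
  tab <- taskTable("DP", vapply(smiles, canonicalSmiles, ""),
                   labels = rep(c(0, 1), 6))
  sp <- scaffoldSplit(tab, seed = 1)
  f <- folds(sp)[[1]]
  sc <- provenance(sp)$rowScaffold
  expect_length(intersect(sc[f$train], sc[f$test]), 0L)
  expect_length(intersect(sc[f$train], sc[f$valid]), 0L)
  expect_length(intersect(sc[f$valid], sc[f$test]), 0L)
  expect_equal(sort(c(f$train, f$valid, f$test)), seq_along(smiles))
  ## acyclic molecules share the empty-scaffold group
  expect_identical(sc[10], sc[11])
  ## all-distinct scaffolds at n = 10 give 8/1/1
  ten <- c("c1ccccc1C", "C1CCCCC1C", "C1CCCC1C", "C1CC1C", "C1CCCCCC1C",
           "C1COCC1C", "C1CCNCC1C", "C1CCSCC1C", "C1CNCC1C", "C1COC1C")
  spT <- scaffoldSplit(ten, seed = 1)
  fT <- folds(spT)[[1]]
  expect_equal(lengths(fT[c("train", "valid", "test")]),
               c(train = 8L, valid = 1L, test = 1L))
  ## a single scaffold group cannot satisfy the ratios
  expect_error(scaffoldSplit(c("CCO", "CC", "CCCC")), "scaffold group")
})

test_that("ppi traversal splits isolate collected proteins in test", {
  set.seed(13)
  prots <- paste0("p", 1:20)
  edges <- t(utils::combn(20, 2))
  edges <- edges[sample(nrow(edges), 60), ]
  rows <- list(left = prots[edges[, 1]], right = prots[edges[, 2]])
  for (strat in c("bfs", "dfs")) {
    sp <- ppiGraphSplit(rows, strat, testRatio = 0.2, seed = 4)
    f <- folds(sp)[[1]]
    coll <- provenance(sp)$collected
    expect_true(all(rows$left[f$test] %in% coll |
                      rows$right[f$test] %in% coll))
    expect_false(any(rows$left[f$train] %in% coll |
                       rows$right[f$train] %in% coll))
    expect_gte(provenance(sp)$achievedRatio, 0.2)
    ## determinism
    sp2 <- ppiGraphSplit(rows, strat, testRatio = 0.2, seed = 4)
    expect_identical(folds(sp2), folds(sp))
  }
  ## path graph, BFS: collected proteins form a contiguous ball
  pr <- list(left = paste0("p", 1:9), right = paste0("p", 2:10))
  spB <- ppiGraphSplit(pr, "bfs", testRatio = 0.2, seed = 2)
  coll <- match(provenance(spB)$collected, paste0("p", 1:10))
  expect_equal(sort(coll), seq(min(coll), max(coll)))
})

test_that("split serialization round-trips", {
  rows <- mkRows()
  sp <- makeInteractionSplit(rows, "cold_cluster", seed = 9)
  f <- tempfile(fileext = ".json")
  writeSplitSpec(sp, f)
  sp2 <- readSplitSpec(f)
  expect_identical(strategy(sp2), strategy(sp))
  expect_equal(folds(sp2), folds(sp))
})

test_that("auroc equals the concordant-pair oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8), c(1, 0)), 1.0)
  set.seed(17)
  for (trial in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # force ties sometimes
    expect_equal(auroc(scores, labels), aurocOracle(scores, labels))
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("aupr matches the threshold-sweep oracle", {
  set.seed(19)
  for (trial in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))
    expect_lt(abs(aupr(scores, labels) - auprOracle(scores, labels)),
              1e-9)
  }
  expect_error(aupr(c(0.1), c(1)), "both classes")
})

test_that("micro-F1 pools decisions and handles missing labels", {
  probs <- matrix(c(0.9, 0.1, 0.8, 0.3), 2, 2)
  labels <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(microF1(probs, labels), 1.0)
  labels2 <- matrix(c(1, 0, 0, 1), 2, 2)
  ## tp = 1 (0.9), fp = 1 (0.8), fn = 1 (the 0.3 on a positive)
  expect_equal(microF1(probs, labels2), 2 * 1 / (2 * 1 + 1 + 1))
  labNA <- labels2; labNA[2, 2] <- NA
  expect_equal(microF1(probs, labNA), 2 / (2 + 1 + 0))
})
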