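test_that("removeTestLinks drops every triplet over a test pair", {
  kb <- toyKb()
  out <- removeTestLinks(kb, rbind(c("d1", "p1")))
  expect_identical(entities(out), entities(kb))
  expect_false(any(out@triplets$h == "d1" & out@triplets$t == "p1"))
  expect_equal(nrow(triplets(out)), nrow(triplets(kb)) - 1L)

  ## empty pair set is the identity
  same <- removeTestLinks(kb, matrix(character(), ncol = 2))
  expect_identical(triplets(same), triplets(kb))

  ## unordered match removes both orientations, any relation
  kb2 <- knowledgeBase(c("a", "b"), c("r1", "r2"), c("b", "a"))
  out2 <- removeTestLinks(kb2, rbind(c("a", "b")))
  expect_equal(nrow(triplets(out2)), 0L)
  expect_identical(entities(out2), c("a", "b"))

  ## pairs absent from the kb are ignored
  out3 <- removeTestLinks(kb, rbind(c("zz", "qq")))
  expect_identical(triplets(out3), triplets(kb))
})

test_that("buildAdjacency collapses multigraphs and drops self-loops", {
  kb <- knowledgeBase("a", "r", "b")
  A <- buildAdjacency(kb)
  expect_equal(dim(A), c(2L, 2L))
  expect_equal(A[1, 2], 1)
  expect_equal(A[2, 1], 1)
  expect_equal(A[1, 1], 0)

  kb2 <- knowledgeBase(c("a", "a"), c("r1", "r2"), c("b", "b"))
  expect_equal(Matrix::nnzero(buildAdjacency(kb2)), 2L)  # one edge

  kb3 <- knowledgeBase(c("a", "b", "c"), rep("r", 3), c("b", "c", "a"))
  expect_equal(unname(Matrix::rowSums(buildAdjacency(kb3))), c(2, 2, 2))

  ## self-loops dropped
  kb4 <- knowledgeBase(c("a", "a"), c("r", "r"), c("a", "b"))
  expect_equal(Matrix::nnzero(buildAdjacency(kb4)), 2L)
})

test_that("tsvdEmbed reconstructs exact-rank matrices and zeroes isolates", {
  ## two disjoint identical edges: the spectrum is fully degenerate, so
  ## individual rows are only defined up to an orthogonal transform. The
  ## basis-independent object is the Gram matrix E E^T, which must be
  ## invariant under the automorphism that swaps the two edges.
  kb <- knowledgeBase(c("a", "c"), c("r", "r"), c("b", "d"))
  A <- buildAdjacency(kb)
  E <- tsvdEmbed(A, dKg = 4, seed = 1)
  G <- tcrossprod(E[, ], E[, ])
  perm <- c(3, 4, 1, 2)          # swap edge (a,b) with edge (c,d)
  expect_equal(G[perm, perm], G, tolerance = 1e-8)
  expect_equal(sum(E[1, ]^2), sum(E[3, ]^2), tolerance = 1e-8)

  ## rank-r reconstruction against the dense SVD oracle
  set.seed(31)
  for (n in c(20, 60, 100)) {
    kbR <- {
      i <- sample(n, n * 2, replace = TRUE)
      j <- sample(n, n * 2, replace = TRUE)
      keep <- i != j
      knowledgeBase(paste0("e", i[keep]), rep("r", sum(keep)),
                    paste0("e", j[keep]),
                    entities = paste0("e", seq_len(n)))
    }
    A <- buildAdjacency(kbR)
    deg <- Matrix::rowSums(A)
    An <- as.matrix(A) / ifelse(deg > 0, deg, 1)
    An[deg == 0, ] <- 0
    r <- qr(An)$rank
    E <- tsvdEmbed(A, dKg = r, seed = 7)
    rec <- attr(E, "u") %*% diag(attr(E, "d"), r) %*% t(attr(E, "v"))
    expect_lt(norm(rec - An, "F") / max(norm(An, "F"), 1e-12), 1e-6)
    ## oracle: dense SVD agrees on singular values
    sv <- svd(An)$d[seq_len(r)]
    expect_lt(max(abs(sv - attr(E, "d"))), 1e-6)
  }

  ## isolated node gets an all-zero row
  kbI <- knowledgeBase("a", "r", "b", entities = c("a", "b", "iso"))
  Ei <- tsvdEmbed(buildAdjacency(kbI), dKg = 2, seed = 1)
  expect_true(all(Ei[3, ] == 0))

  ## contract error when dKg exceeds |E|
  expect_error(tsvdEmbed(buildAdjacency(kbI), dKg = 5), "exceeds")
})

test_that("spectralPropagate matches the dense Chebyshev oracle", {
  set.seed(41)
  n <- 30
  i <- sample(n, 60, replace = TRUE); j <- sample(n, 60, replace = TRUE)
  keep <- i != j
  kb <- knowledgeBase(paste0("e", i[keep]), rep("r", sum(keep)),
                      paste0("e", j[keep]),
                      entities = paste0("e", seq_len(n)))
  A <- buildAdjacency(kb)
  X <- matrix(rnorm(n * 5), n, 5)
  got <- spectralPropagate(X, A, order = 10, theta = 0.5, mu = 0.2)
  ref <- spectralOracle(X, A, order = 10, theta = 0.5, mu = 0.2)
  expect_lt(max(abs(got - as.matrix(ref))), 1e-8)

  ## order 0 is a pure scaling of the input
  h0 <- spectralPropagate(X, A, order = 0)
  expect_equal(h0 / X, matrix(h0[1] / X[1], n, 5), tolerance = 1e-12)

  ## a graph with no edges short-circuits to the order-0 scaling
  kbE <- knowledgeBase(entities = paste0("e", 1:4))
  Xe <- matrix(rnorm(8), 4, 2)
  expect_equal(spectralPropagate(Xe, buildAdjacency(kbE), order = 7),
               spectralPropagate(Xe, buildAdjacency(kbE), order = 0))

  ## finiteness and shape across orders on larger random graphs
  for (ord in c(0, 1, 8, 16)) {
    h <- spectralPropagate(X, A, order = ord)
    expect_true(all(is.finite(h)))
    expect_equal(dim(h), dim(X))
  }
  expect_error(spectralPropagate(X, A, order = -1), "order")
})

test_that("kgEmbed is deterministic and respects entity order", {
  corpus <- sharedCorpus()
  kb <- storeKb(corpusStore(corpus))
  e1 <- kgEmbed(kb, dKg = 16, seed = 9)
  e2 <- kgEmbed(kb, dKg = 16, seed = 9)
  expect_identical(embeddingMatrix(e1), embeddingMatrix(e2))
  expect_identical(names(e1@entityIndex), entities(kb))

  ## lookup returns the exact row; unknown ids are typed misses
  id <- entities(kb)[5]
  expect_identical(lookupEmbedding(e1, id),
                   embeddingMatrix(e1)[5, ])
  expect_true(isKgMiss(lookupEmbedding(e1, "no-such-entity")))

  ## row count is unchanged by leakage removal
  pairs <- rbind(entities(kb)[1:2])
  e3 <- kgEmbed(kb, dKg = 16, testPairs = pairs, seed = 9)
  expect_equal(nrow(embeddingMatrix(e3)), length(entities(kb)))
})

test_that("embeddings of same-orbit nodes have equal norms", {
  ## vertex-transitive fixtures; the truncation width is chosen to keep
  ## whole degenerate eigenspaces (a cut inside a degenerate group would
  ## make individual rows basis-dependent)
  n <- 8   # cycle: the two |sigma| = 1 vectors form a closed group
  kb <- knowledgeBase(paste0("v", 1:n), rep("r", n),
                      paste0("v", c(2:n, 1)))
  E <- embeddingMatrix(kgEmbed(kb, dKg = 2, seed = 3))
  norms <- sqrt(rowSums(E^2))
  expect_lt(max(norms) - min(norms), 1e-8)

  ## complete graph: leading eigenvector alone
  pr <- t(utils::combn(5, 2))
  kbK <- knowledgeBase(paste0("k", pr[, 1]), rep("r", nrow(pr)),
                       paste0("k", pr[, 2]))
  Ek <- embeddingMatrix(kgEmbed(kbK, dKg = 1, seed = 3))
  nk <- sqrt(rowSums(Ek^2))
  expect_lt(max(nk) - min(nk), 1e-8)
})

test_that("embedding export/import round-trips matrix and provenance", {
  kb <- toyKb()
  emb <- kgEmbed(kb, dKg = 3, seed = 2,
                 testPairs = rbind(c("d1", "p2")))
  d <- tempfile()
  exportKgEmbedding(emb, d)
  emb2 <- importKgEmbedding(d)
  expect_equal(embeddingMatrix(emb2), embeddingMatrix(emb),
               tolerance = 1e-12)
  expect_identical(names(emb2@entityIndex), names(emb@entityIndex))
  expect_equal(provenance(emb2)$dKg, 3)
  expect_equal(provenance(emb2)$seed, 2)
})
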