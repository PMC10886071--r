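## Evaluation splits: warm / cold-drug / cold-protein / cold-cluster
## cross-validation, random 8:1:1, Bemis-Murcko scaffold split, and
## BFS/DFS traversal splits of the protein-protein interaction graph.
## Every SplitSpec re-validates its own strategy invariant on
## construction, so a violating split cannot be instantiated.

## Validity hook for SplitSpec: checks fold disjointness and the
## strategy-specific entity-level guarantees recorded in provenance.
validateSplitSpec <- function(object) {
  msg <- character()
  st <- object@strategy
  pv <- object@provenance
  for (f in object@folds) {
    if (length(intersect(f$train, f$test)) ||
        length(intersect(f$train, f$valid)) ||
        length(intersect(f$valid, f$test)))
      msg <- c(msg, "train/valid/test of a fold must be disjoint")
  }
  left <- pv$rowLeft
  right <- pv$rowRight
  if (st %in% c("cold_drug", "cold_protein") && !is.null(left)) {
    ent <- if (st == "cold_drug") left else right
    for (f in object@folds) {
      if (length(intersect(ent[f$train], ent[f$test])))
        msg <- c(msg, paste0(st, ": held-out entities leak into training"))
    }
  }
  if (st == "cold_cluster" && !is.null(left)) {
    for (f in object@folds) {
      if (length(intersect(left[f$train], left[f$test])) ||
          length(intersect(right[f$train], right[f$test])))
        msg <- c(msg, "cold_cluster: test entities leak into training")
    }
  }
  if (st == "scaffold" && !is.null(pv$rowScaffold)) {
    sc <- pv$rowScaffold
    for (f in object@folds) {
      parts <- list(f$train, f$valid, f$test)
      for (a in 1:2) for (b in (a + 1):3) {
        if (length(intersect(sc[parts[[a]]], sc[parts[[b]]])))
          msg <- c(msg, "scaffold: a scaffold spans two partitions")
      }
    }
  }
  if (st %in% c("ppi_bfs", "ppi_dfs") && !is.null(pv$collected)) {
    for (f in object@folds) {
      if (!all(left[f$test] %in% pv$collected |
               right[f$test] %in% pv$collected))
        msg <- c(msg, "ppi split: test rows must touch collected proteins")
      if (any(left[f$train] %in% pv$collected |
              right[f$train] %in% pv$collected))
        msg <- c(msg, "ppi split: rows touching collected proteins must not train")
    }
  }
  if (length(msg)) msg else TRUE
}

newSplitSpec <- function(strategy, folds, seed, provenance) {
  new("SplitSpec", strategy = strategy, folds = folds,
      seed = as.integer(seed), provenance = provenance)
}

## Seeded partition of x into n groups of near-equal size.
partitionSet <- function(x, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sample(x)
  split(x, rep(seq_len(n), length.out = length(x)))
}

#' Cross-validation splits for interaction tables
#'
#' Strategies:
#' * `warm`: random partition of rows into `nFolds`; one rotating
#'   non-test fold serves as validation.
#' * `cold_drug` / `cold_protein`: the drug (protein) set is partitioned;
#'   a fold's test rows are the rows whose drug (protein) is held out, so
#'   test entities are never seen in training.
#' * `cold_cluster`: drugs are partitioned into 3 groups and proteins into
#'   3 groups; the 9 folds are the group products. Test rows lie in the
#'   product cell; training rows have both entities from other groups;
#'   rows sharing exactly one group with the cell are discarded and a
#'   seeded 10% of training rows is used for validation.
#' * `random_811`: single 8:1:1 train/valid/test split.
#'
#' @param rows a [TaskTable-class] or list with `left`/`right` key vectors.
#' @param strategy one of the above.
#' @param nFolds fold count (5 for warm/cold entity splits; cold_cluster
#'   always yields 9).
#' @param seed RNG seed; splits are deterministic per seed and invariant
#'   to row order.
#' @return a [SplitSpec-class].
#' @export
makeInteractionSplit <- function(rows,
                                 strategy = c("warm", "cold_drug",
                                              "cold_protein",
                                              "cold_cluster",
                                              "random_811"),
                                 nFolds = 5L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (is(rows, "TaskTable")) {
    keys <- taskKeys(rows)
    left <- keys$left
    right <- if (length(keys$right)) keys$right else NULL
  } else {
    left <- rows$left
    right <- rows$right
  }
  n <- length(left)
  ## row-order invariance: operate on entity sets sorted before shuffling
  if (strategy == "warm") {
    set.seed(seed)
    ord <- sample.int(n)
    foldOf <- integer(n)
    foldOf[ord] <- rep(seq_len(nFolds), length.out = n)
    folds <- lapply(seq_len(nFolds), function(f) {
      vf <- (f %% nFolds) + 1L
      list(train = which(!foldOf %in% c(f, vf)),
           valid = which(foldOf == vf),
           test = which(foldOf == f))
    })
  } else if (strategy == "random_811") {
    set.seed(seed)
    ord <- sample.int(n)
    nTr <- floor(0.8 * n); nVa <- floor(0.1 * n)
    folds <- list(list(train = sort(ord[seq_len(nTr)]),
                       valid = sort(ord[nTr + seq_len(nVa)]),
                       test = sort(ord[(nTr + nVa + 1L):n])))
  } else if (strategy %in% c("cold_drug", "cold_protein")) {
    ent <- if (strategy == "cold_drug") left else {
      if (is.null(right)) stop("cold_protein needs right-side keys")
      right
    }
    uents <- sort(unique(ent))
    if (length(uents) < nFolds)
      stop("fewer distinct entities (", length(uents),
           ") than folds (", nFolds, ")")
    groups <- partitionSet(uents, nFolds, seed = seed)
    gOf <- integer(length(uents))
    names(gOf) <- unlist(groups)
    gOf[unlist(groups)] <- rep(seq_along(groups), lengths(groups))
    rowG <- unname(gOf[ent])
    folds <- lapply(seq_len(nFolds), function(f) {
      vf <- (f %% nFolds) + 1L
      list(train = which(!rowG %in% c(f, vf)),
           valid = which(rowG == vf),
           test = which(rowG == f))
    })
  } else {  # cold_cluster
    if (is.null(right)) stop("cold_cluster needs right-side keys")
    ud <- sort(unique(left)); up <- sort(unique(right))
    if (length(ud) < 3L || length(up) < 3L)
      stop("cold_cluster needs at least 3 distinct drugs and proteins")
    gd <- partitionSet(ud, 3L, seed = deriveSeed(seed, "drug"))
    gp <- partitionSet(up, 3L, seed = deriveSeed(seed, "protein"))
    dOf <- integer(length(ud)); names(dOf) <- unlist(gd)
    dOf[unlist(gd)] <- rep(1:3, lengths(gd))
    pOf <- integer(length(up)); names(pOf) <- unlist(gp)
    pOf[unlist(gp)] <- rep(1:3, lengths(gp))
    rd <- unname(dOf[left]); rp <- unname(pOf[right])
    folds <- list()
    set.seed(deriveSeed(seed, "valid"))
    for (a in 1:3) for (b in 1:3) {
      test <- which(rd == a & rp == b)
      trainAll <- which(rd != a & rp != b)
      nv <- max(1L, floor(0.1 * length(trainAll)))
      valid <- sort(sample(trainAll, nv))
      folds[[length(folds) + 1L]] <-
        list(train = setdiff(trainAll, valid), valid = valid,
             test = test)
    }
  }
  pv <- list(nFolds = length(folds), rowLeft = left, rowRight = right)
  newSplitSpec(strategy, folds, seed, pv)
}

#' Scaffold split of a drug table (8:1:1)
#'
#' Molecules are grouped by Bemis-Murcko scaffold ([scaffoldKey()]); groups
#' are sorted by descending size and assigned whole to train until the
#' train quota is met, then valid, then test, so no scaffold spans two
#' partitions.
#'
#' @param rows a DP [TaskTable-class] or character vector of SMILES keys.
#' @param ratios train/valid/test fractions (default `c(8, 1, 1) / 10`).
#' @param seed stored for provenance (the greedy assignment itself is
#'   deterministic; ties in group size break by first occurrence).
#' @return a [SplitSpec-class].
#' @export
scaffoldSplit <- function(rows, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  keys <- if (is(rows, "TaskTable")) taskKeys(rows)$left
          else as.character(rows)
  n <- length(keys)
  sc <- vapply(keys, function(k) scaffoldKey(k), "", USE.NAMES = FALSE)
  groups <- split(seq_len(n), factor(sc, levels = unique(sc)))
  if (length(groups) < 3L)
    stop("cannot satisfy the split ratios: only ", length(groups),
         " scaffold group(s) cover all molecules")
  ord <- order(-lengths(groups), seq_along(groups))
  nTrain <- floor(ratios[1] * n)
  nValid <- max(1L, round(ratios[2] * n))
  assign <- list(train = integer(), valid = integer(), test = integer())
  for (gi in ord) {
    g <- groups[[gi]]
    part <- if (length(assign$train) < nTrain) "train"
            else if (length(assign$valid) < nValid) "valid"
            else "test"
    assign[[part]] <- c(assign[[part]], g)
  }
  if (!length(assign$test) || !length(assign$valid))
    stop("cannot satisfy the split ratios: a dominant scaffold group ",
         "absorbs the quota")
  folds <- list(list(train = sort(assign$train),
                     valid = sort(assign$valid),
                     test = sort(assign$test)))
  newSplitSpec("scaffold", folds, seed,
               list(ratios = ratios, rowScaffold = sc,
                    nScaffolds = length(groups)))
}

#' BFS/DFS traversal split of a protein-protein interaction table
#'
#' Builds the protein interaction graph, traverses it from a seeded random
#' root (breadth-first or depth-first) collecting proteins until the rows
#' touching the collected set reach `testRatio`, and assigns those rows to
#' test. When a component is exhausted before the quota, traversal
#' restarts from a fresh random root. The achieved ratio is reported in
#' provenance.
#'
#' @param rows a PPI [TaskTable-class] or list with `left`/`right`.
#' @param strategy `"bfs"` or `"dfs"`.
#' @param testRatio target fraction of rows in test (default 0.2).
#' @param seed RNG seed (root choice and neighbor order).
#' @param maxRestarts safety cap on traversal restarts.
#' @return a [SplitSpec-class] with one fold (train/test; valid empty).
#' @export
ppiGraphSplit <- function(rows, strategy = c("bfs", "dfs"),
                          testRatio = 0.2, seed = 1L,
                          maxRestarts = 100L) {
  strategy <- match.arg(strategy)
  if (is(rows, "TaskTable")) {
    keys <- taskKeys(rows)
    left <- keys$left; right <- keys$right
  } else {
    left <- rows$left; right <- rows$right
  }
  n <- length(left)
  prot <- sort(unique(c(left, right)))
  adj <- lapply(seq_along(prot), function(i) integer())
  names(adj) <- prot
  li <- match(left, prot); ri <- match(right, prot)
  for (i in seq_len(n)) {
    adj[[li[i]]] <- c(adj[[li[i]]], ri[i])
    adj[[ri[i]]] <- c(adj[[ri[i]]], li[i])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  set.seed(seed)
  target <- testRatio * n
  collected <- integer()
  visited <- rep(FALSE, length(prot))
  testRows <- logical(n)
  restarts <- 0L
  frontier <- integer()
  while (sum(testRows) < target) {
    if (!length(frontier)) {
      cand <- which(!visited)
      if (!length(cand) || restarts >= maxRestarts) break
      frontier <- if (length(cand) == 1L) cand else sample(cand, 1L)
      restarts <- restarts + 1L
    }
    cur <- if (strategy == "bfs") frontier[1] else frontier[length(frontier)]
    frontier <- if (strategy == "bfs") frontier[-1]
                else frontier[-length(frontier)]
    if (visited[cur]) next
    visited[cur] <- TRUE
    collected <- c(collected, cur)
    testRows <- testRows | (li == cur) | (ri == cur)
    nb <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(nb) > 1L) nb <- sample(nb)
    frontier <- if (strategy == "bfs") c(frontier, nb) else c(frontier, nb)
  }
  if (sum(testRows) < target && restarts >= maxRestarts)
    stop("ppi split: could not reach the test quota within ",
         maxRestarts, " traversal restarts")
  folds <- list(list(train = which(!testRows), valid = integer(),
                     test = which(testRows)))
  newSplitSpec(paste0("ppi_", strategy), folds, seed,
               list(testRatio = testRatio,
                    achievedRatio = sum(testRows) / n,
                    collected = prot[collected],
                    rowLeft = left, rowRight = right))
}

#' Serialize a SplitSpec to JSON
#'
#' @param split a [SplitSpec-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSplitSpec <- function(split, path) {
  obj <- list(strategy = strategy(split), seed = split@seed,
              folds = folds(split), provenance = provenance(split))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a SplitSpec written by [writeSplitSpec()]
#'
#' @param path JSON path.
#' @return a [SplitSpec-class].
#' @export
readSplitSpec <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  folds <- lapply(obj$folds, function(f)
    list(train = as.integer(unlist(f$train)),
         valid = as.integer(unlist(f$valid)),
         test = as.integer(unlist(f$test))))
  pv <- obj$provenance
  pv$rowLeft <- as.character(unlist(pv$rowLeft))
  if (!is.null(pv$rowRight)) pv$rowRight <- as.character(unlist(pv$rowRight))
  if (!is.null(pv$collected)) pv$collected <- as.character(unlist(pv$collected))
  if (!is.null(pv$rowScaffold)) pv$rowScaffold <- as.character(unlist(pv$rowScaffold))
  newSplitSpec(obj$strategy, folds, obj$seed, pv)
}
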