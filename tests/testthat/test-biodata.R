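test_that("parseMolecule builds atom/bond categories and canonical keys", {
  m <- parseMolecule("C")
  expect_equal(nrow(atoms(m)), 1L)
  expect_equal(nrow(bonds(m)), 0L)

  m <- parseMolecule("CCO")
  expect_equal(nrow(atoms(m)), 3L)
  expect_equal(nrow(bonds(m)), 2L)
  expect_setequal(atoms(m)$type, c("C", "O"))
  expect_true(all(bonds(m)$type == "single"))
  expect_true(all(bonds(m)$u != bonds(m)$v))
  expect_true(all(c(bonds(m)$u, bonds(m)$v) %in% seq_len(3)))

  expect_error(parseMolecule("C("), "unbalanced parenthesis")
  expect_error(parseMolecule("C1CC"), "unmatched ring bond")
  expect_error(parseMolecule("Xx"), "invalid SMILES")
  expect_error(parseMolecule(""), "nonempty")
})

test_that("canonicalization is idempotent and spelling-invariant", {
  spellings <- c("OCC", "CCO", "C(O)C")
  keys <- vapply(spellings, canonicalSmiles, "")
  expect_length(unique(keys), 1L)
  ## idempotence: canonicalizing the canonical form is a fixed point
  expect_identical(canonicalSmiles(keys[1]), unname(keys[1]))
  ## parseMolecule agrees with canonicalSmiles
  expect_identical(canonicalKey(parseMolecule("OCC")), unname(keys[1]))
  ## chirality tags are captured per atom
  chir <- atoms(parseMolecule("N[C@@H](C)O"))$chirality
  expect_true("cw" %in% chir)
})

test_that("FASTA protein IO round-trips ids and residues", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKV", ">p2", "GGX"), f)
  ps <- readFastaProteins(f)
  expect_length(ps, 2L)
  expect_identical(seqId(ps[[1]]), "p1")
  expect_identical(residues(ps[[1]]), "MKV")
  expect_identical(canonicalKey(ps[[2]]), "GGX")
  ## round trip
  f2 <- tempfile(fileext = ".fasta")
  writeFastaProteins(ps, f2)
  ps2 <- readFastaProteins(f2)
  expect_identical(vapply(ps2, seqId, ""), vapply(ps, seqId, ""))
  expect_identical(vapply(ps2, residues, ""), vapply(ps, residues, ""))
  ## lowercase input uppercased; unknown residues mapped to X
  expect_identical(residues(proteinSequence("x", "mkz")), "MKX")
  ## failure modes
  f3 <- tempfile(fileext = ".fasta")
  writeLines(">a", f3)
  expect_error(readFastaProteins(f3), "format error")
  expect_error(readFastaProteins(tempfile()), "not found")
})

test_that("knowledge base TSV loading dedupes and keeps entity order", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("a\tbinds\tb"), f)
  kb <- loadKnowledgeBase(f)
  expect_identical(entities(kb), c("a", "b"))
  expect_equal(nrow(triplets(kb)), 1L)

  writeLines(c("a\tbinds\tb", "a\tbinds\tb"), f)
  expect_equal(nrow(triplets(loadKnowledgeBase(f))), 1L)

  writeLines(c("a\tbinds\tb", "c\tbinds"), f)
  expect_error(loadKnowledgeBase(f), "line 2")

  ## first-appearance entity order is reproducible
  writeLines(c("z\tr\ta", "b\tr\tz", "a\tr\tb"), f)
  kb1 <- loadKnowledgeBase(f)
  kb2 <- loadKnowledgeBase(f)
  expect_identical(entities(kb1), c("z", "a", "b"))
  expect_identical(entities(kb1), entities(kb2))
  ## header recognized
  writeLines(c("head\trelation\ttail", "a\tr\tb"), f)
  expect_equal(nrow(triplets(loadKnowledgeBase(f))), 1L)
  ## round trip preserves the triplet multiset up to dedup
  f4 <- tempfile(fileext = ".tsv")
  writeKnowledgeBase(kb1, f4)
  kb3 <- loadKnowledgeBase(f4)
  expect_identical(triplets(kb3), triplets(kb1))
})

test_that("text JSONL and task table IO round-trip", {
  f <- tempfile(fileext = ".jsonl")
  writeTextRecords(c(e1 = "an ACE inhibitor", e2 = ""), f)
  tr <- readTextRecords(f)
  expect_identical(tr$entity_id, c("e1", "e2"))
  expect_identical(tr$text, c("an ACE inhibitor", ""))

  tab <- taskTable("DTI", c("CCO", "CC"), c("MKV", "GGG"), c(1, 0))
  f2 <- tempfile(fileext = ".csv")
  writeTaskTable(tab, f2)
  tab2 <- readTaskTable(f2, "DTI")
  expect_identical(taskKeys(tab2), taskKeys(tab))
  expect_equal(unname(taskLabels(tab2)), unname(taskLabels(tab)))

  ## multi-task DP with missing labels
  lab <- matrix(c(1, NA, 0, 1), 2, 2)
  dp <- taskTable("DP", c("C", "CC"), labels = lab)
  f3 <- tempfile(fileext = ".csv")
  writeTaskTable(dp, f3)
  dp2 <- readTaskTable(f3, "DP")
  expect_equal(unname(taskLabels(dp2)), unname(lab))
  ## missing labels rejected outside multi-task DP
  expect_error(taskTable("DTI", "C", "M", NA), "missing labels")
})

test_that("scaffold keys group by Bemis-Murcko framework", {
  expect_identical(scaffoldKey("c1ccccc1CC"), scaffoldKey("c1ccccc1CCC"))
  expect_identical(scaffoldKey("CCO"), "")
  expect_identical(scaffoldKey("CC(C)CC"), "")
  ## different ring systems get different keys
  expect_false(scaffoldKey("c1ccccc1C") == scaffoldKey("C1CC1C"))
  ## substituent position does not change the framework
  expect_identical(scaffoldKey("CC1CCCCC1"), scaffoldKey("C1CCCCC1CC"))
})
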