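test_that("readFasta normalizes case and RNA and keeps record order", {
  f <- writeFastaLines(c(">a first", "acgu", ">b", "AC", "GT"))
  s <- readFasta(f)
  expect_identical(names(s), c("a", "b"))
  expect_identical(as.character(s), c(a = "ACGT", b = "ACGT"))
})

test_that("readFasta accepts IUPAC ambiguity codes but rejects other letters", {
  ok <- readFasta(writeFastaLines(c(">r", "ACGR")))
  expect_identical(as.character(ok)[[1]], "ACGR")
  f <- writeFastaLines(c(">r1", "ACGT", ">r2", "ACGX"))
  expect_error(readFasta(f), "line 4")
  expect_error(readFasta(writeFastaLines(character(0))), "empty")
  expect_error(readFasta(writeFastaLines(c("ACGT", ">x", "AC"))), "line 1")
})

test_that("write/read FASTA round-trips normalized records", {
  set.seed(31)
  ids <- sprintf("rec%02d", 1:8)
  seqs <- vapply(1:8, function(i) randomIupacString(90), character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  f <- tempfile(fileext = ".fasta")
  writeFasta(dss, f, width = 37L)
  back <- readFasta(f)
  expect_identical(as.character(back), setNames(seqs, ids))
})

test_that("parseTaxonomy strips prefixes, trims, pads and validates", {
  f <- writeTaxLines(c(
    "id1\td__Bacteria; p__P; c__C; o__O; f__F; g__G; s__G_sp1",
    "id2\td__Bacteria;p__P2",
    "id3\td__Bacteria"))
  tx <- parseTaxonomy(f)
  expect_identical(unname(tx[["id1"]]),
                   c("Bacteria", "P", "C", "O", "F", "G", "G_sp1"))
  expect_identical(unname(tx[["id2"]]),
                   c("Bacteria", "P2", "", "", "", "", ""))
  expect_identical(sum(tx[["id3"]] == ""), 6L)
  expect_error(parseTaxonomy(writeTaxLines(c("a\td__B", "a\td__B"))),
               "duplicate")
  expect_error(
    parseTaxonomy(writeTaxLines("a\td__1; p__2; c__3; o__4; f__5; g__6; s__7; x__8")),
    "8 ranks")
})

test_that("taxonomy writer round-trips through the parser", {
  ds <- toyBandDataset(sizes = c(2L, 3L), withAmbiguity = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeTaxonomy(ds, f)
  tx <- parseTaxonomy(f)
  expect_identical(names(tx), names(ds))
  expect_identical(unname(tx[[1]]), as.character(as.data.frame(taxonomy(ds)[1, ])))
})

test_that("joinDataset inner-joins, drops unlabeled records and builds labels", {
  f <- writeFastaLines(c(">a", "ACGT", ">b", "ACGA", ">c", "ACGC", ">d", "ACGG"))
  seqs <- readFasta(f)
  tx <- list(a = rankRow("G1", "G1_sp1"), b = rankRow("G1", "G1_sp2"),
             c = rankRow("G2", ""))
  names(tx$a) <- names(tx$b) <- names(tx$c) <- DSNetax:::RANK_NAMES
  expect_message(ds <- joinDataset(seqs, tx), "dropped 2")
  expect_identical(length(ds), 2L)
  li <- labelIndex(ds)
  expect_identical(li$label, 0:1)
  expect_identical(sort(li$species), c("G1_sp1", "G1_sp2"))
  # keepUnlabeled retains the empty-species record for genus-level runs
  expect_message(ds2 <- joinDataset(seqs, tx, keepUnlabeled = TRUE),
                 "dropped 1")
  expect_identical(length(ds2), 3L)
  # all ids matching and labeled: size preserved, duplicate species dedup'd
  tx$c <- tx$a
  tx$d <- tx$a
  ds3 <- joinDataset(seqs, tx)
  expect_identical(length(ds3), 4L)
  expect_identical(nrow(labelIndex(ds3)), 2L)
  expect_error(joinDataset(seqs, list()), "no records")
})

test_that("dataset container enforces its invariants", {
  expect_error(makeDataset(c("a", "a"), c("ACGT", "ACGT"),
                           rbind(rankRow("G", "s1"), rankRow("G", "s2"))),
               "unique")
  ds <- toyBandDataset(sizes = c(2L, 2L))
  sub <- ds[c(1L, 3L)]
  expect_identical(length(sub), 2L)
  expect_identical(names(sub), names(ds)[c(1L, 3L)])
  expect_identical(sub@labelIndex, ds@labelIndex)
  expect_identical(names(ds["sp2_r1"]), "sp2_r1")
})
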