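test_that("simulateTaxonomy builds unique species nested in genera", {
  cfg <- simConfig(nSpecies = 10L, speciesPerGenus = 5L, seed = 3L)
  tax <- simulateTaxonomy(cfg)
  expect_identical(nrow(tax), 10L)
  expect_false(anyDuplicated(tax[, "species"]) > 0)
  expect_identical(as.integer(table(tax[, "genus"])[c("Genus1", "Genus2")]),
                   c(5L, 5L))
  expect_identical(simulateTaxonomy(cfg), tax)
})

test_that("references diverge by the configured sister distance", {
  cfg0 <- simConfig(nSpecies = 4L, divergence = 0, seqLength = 300L, seed = 5L)
  refs0 <- simulateReferences(simulateTaxonomy(cfg0), cfg0)
  expect_identical(length(unique(refs0)), 1L)
  expect_true(all(nchar(refs0) == 300L))
  cfg <- simConfig(nSpecies = 8L, speciesPerGenus = 4L, divergence = 0.10,
                   seqLength = 1500L, seed = 6L)
  tax <- simulateTaxonomy(cfg)
  refs <- simulateReferences(tax, cfg)
  pdiff <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  sisters <- c(pdiff(refs[["Genus1_sp1"]], refs[["Genus1_sp2"]]),
               pdiff(refs[["Genus1_sp3"]], refs[["Genus1_sp4"]]),
               pdiff(refs[["Genus2_sp1"]], refs[["Genus2_sp2"]]))
  expect_equal(mean(sisters), 0.10, tolerance = 0.1)
  expect_true(all(abs(sisters - 0.10) < 0.025))
  # cross-genus pairs are clearly more distant than sisters
  expect_gt(pdiff(refs[["Genus1_sp1"]], refs[["Genus2_sp1"]]), mean(sisters))
})

test_that("sampleReads draws a long-tailed community with compatible ambiguity", {
  # withinRate 0 so each read equals its reference away from ambiguity sites,
  # making the compatible-code invariant directly checkable
  cfg <- simConfig(nSpecies = 9L, seqLength = 150L, minCount = 1L,
                   maxCount = 60L, withinRate = 0, ambiguityRate = 0.01,
                   seed = 9L)
  cm <- simulateCommunity(cfg)
  counts <- cm$counts[cm$taxonomy[, "species"]]
  expect_true(all(diff(unname(counts)) <= 0))  # non-increasing by rank
  expect_identical(sum(counts), length(cm$dataset))
  # every replication band is populated (fully exercises preprocessing)
  fac <- replicationFactor(counts)
  expect_setequal(unique(fac), c(12L, 4L, 2L, 1L))
  # ambiguity codes are always compatible with the true reference base
  seqs <- as.character(sequences(cm$dataset))
  sp <- speciesLabels(cm$dataset)
  nAmb <- 0L
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    refc <- strsplit(cm$references[[sp[i]]], "")[[1]]
    amb <- which(!chars %in% c("A", "C", "G", "T"))
    nAmb <- nAmb + length(amb)
    for (j in amb) {
      expect_true(refc[j] %in% DSNetax:::IUPAC_SETS[[chars[j]]])
    }
  }
  expect_gt(nAmb, 0L)
  # ambiguity-free configuration yields pure ACGT reads
  cfg0 <- simConfig(nSpecies = 4L, seqLength = 100L, ambiguityRate = 0,
                    readsPerSpecies = 3L, seed = 2L)
  cm0 <- simulateCommunity(cfg0)
  expect_false(any(grepl("[^ACGT]", as.character(sequences(cm0$dataset)))))
})

test_that("ambiguity resolution recovers the true base at the exact IUPAC rate", {
  # inject a known code, resolve many times, compare with 1/|set|
  set.seed(41)
  for (code in c("R", "N", "B")) {
    sz <- length(DSNetax:::IUPAC_SETS[[code]])
    draws <- vapply(1:3000, function(i) resolveAmbiguous(code), character(1))
    expect_equal(mean(draws == DSNetax:::IUPAC_SETS[[code]][1]), 1 / sz,
                 tolerance = 3 * sqrt((1 / sz) * (1 - 1 / sz) / 3000) * sz)
  }
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- simConfig(nSpecies = 5L, seqLength = 120L, maxCount = 15L, seed = 77L)
  a <- simulateCommunity(cfg)
  b <- simulateCommunity(cfg)
  expect_identical(as.character(sequences(a$dataset)),
                   as.character(sequences(b$dataset)))
  fa <- tempfile(); fb <- tempfile()
  writeFasta(a$dataset, fa); writeFasta(b$dataset, fb)
  expect_identical(readLines(fa), readLines(fb))
  cfg2 <- simConfig(nSpecies = 5L, seqLength = 120L, maxCount = 15L, seed = 78L)
  expect_false(identical(as.character(sequences(simulateCommunity(cfg2)$dataset)),
                         as.character(sequences(a$dataset))))
})

test_that("a generated community flows through the whole pipeline", {
  cm <- benchCommunity(nSpecies = 4L, reads = 6L, len = 80L, seed = 15L)
  # io round trip
  fa <- tempfile(fileext = ".fasta"); tx <- tempfile(fileext = ".tsv")
  writeFasta(cm$dataset, fa); writeTaxonomy(cm$dataset, tx)
  ds <- joinDataset(readFasta(fa), parseTaxonomy(tx))
  expect_identical(length(ds), length(cm$dataset))
  # preprocess, tokenize, embed, classify
  bal <- balanceDataset(ds, seed = 1L)
  sp <- stratifiedSplit(bal, 0.1, seed = 1L)
  v <- buildVocab(3)
  pe <- hashEmbedder(v, dModel = 8L, seed = 1L)
  emb <- embedDataset(sp$test, pe)
  expect_identical(nrow(emb[[1]]), 78L)
  cfg <- dsnetaxConfig(nClasses = 4L, stageWidths = c(4L, 4L, 8L, 8L),
                       stemWidth = 4L, shallowWidth = 4L)
  mdl <- buildModel(cfg, labelIndex = sp$train@labelIndex, seed = 1L)
  logits <- fuseClassify(mdl, deepForward(mdl, emb[1:2]),
                         shallowForward(mdl, emb[1:2]))
  expect_identical(dim(logits), c(4L, 2L))
  expect_true(all(is.finite(logits)))
})
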