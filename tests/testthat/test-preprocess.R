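test_that("countPerSpecies counts multiplicities and conserves the total", {
  ds <- toyBandDataset(sizes = c(2L, 1L, 3L))
  cnt <- countPerSpecies(ds)
  expect_identical(unname(cnt[c("Genus1_sp1", "Genus2_sp1", "Genus3_sp1")]),
                   c(2L, 1L, 3L))
  expect_identical(sum(cnt), length(ds))
  one <- toyBandDataset(sizes = 1L)
  expect_identical(unname(countPerSpecies(one)), 1L)
  expect_error(countPerSpecies(one[0]), "empty")
})

test_that("replicationFactor follows the abundance bands", {
  expect_identical(replicationFactor(c(1, 2)), c(12L, 12L))
  expect_identical(replicationFactor(c(3, 4, 5)), c(4L, 4L, 4L))
  expect_identical(replicationFactor(6:10), rep(2L, 5L))
  expect_identical(replicationFactor(c(11, 12, 500)), c(1L, 1L, 1L))
  expect_error(replicationFactor(0), ">= 1")
  # table must cover 1..threshold-1 without overlap
  expect_error(replicationFactor(1, table = list(list(counts = 1:3, factor = 2))),
               "cover")
})

test_that("resolveAmbiguous only touches ambiguity codes, uniformly", {
  expect_identical(DSNetax:::withSeed(1, resolveAmbiguous("ACGT")), "ACGT")
  r <- DSNetax:::withSeed(5, resolveAmbiguous("ARG"))
  expect_true(r %in% c("AAG", "AGG"))
  expect_identical(r, DSNetax:::withSeed(5, resolveAmbiguous("ARG")))
  expect_error(resolveAmbiguous("ACXG"), "non-IUPAC")
  # property: length and unambiguous positions preserved, output is ACGT
  set.seed(77)
  for (i in 1:25) {
    s <- randomIupacString(120, ambProb = 0.2)
    out <- resolveAmbiguous(s)
    expect_identical(nchar(out), nchar(s))
    expect_false(grepl("[^ACGT]", out))
    plain <- gregexpr("[ACGT]", s)[[1]]
    expect_identical(substring(out, plain, plain), substring(s, plain, plain))
  }
  # each IUPAC set is sampled uniformly
  set.seed(99)
  draws <- vapply(1:4000, function(i) resolveAmbiguous("Y"), character(1))
  expect_equal(mean(draws == "C"), 0.5, tolerance = 0.05)
})

test_that("balanceDataset obeys the conservation law against a naive oracle", {
  set.seed(13)
  for (rep in 1:4) {
    sizes <- sample(1:14, sample(3:6, 1))
    ds <- toyBandDataset(sizes = sizes)
    bal <- balanceDataset(ds, seed = rep)
    # brute-force per-record enumeration oracle
    expected <- 0L
    cnt <- countPerSpecies(ds)
    for (sp in speciesLabels(ds)) {
      n <- cnt[[sp]]
      f <- if (n >= 11) 1L else if (n <= 2) 12L else if (n <= 5) 4L else 2L
      expected <- expected + f
    }
    expect_identical(length(bal), as.integer(expected))
    expect_identical(unname(countPerSpecies(bal)),
                     unname(countPerSpecies(ds) *
                              replicationFactor(countPerSpecies(ds))))
    expect_false(any(grepl("[^ACGT]", as.character(sequences(bal)))))
    expect_false(anyDuplicated(names(bal)) > 0)
  }
})

test_that("balanceDataset is a seeded pure function and a fixed point on clean data", {
  ds <- toyBandDataset(sizes = c(1L, 3L, 11L))
  b1 <- balanceDataset(ds, seed = 42L)
  b2 <- balanceDataset(ds, seed = 42L)
  expect_identical(as.character(sequences(b1)), as.character(sequences(b2)))
  expect_identical(names(b1), names(b2))
  b3 <- balanceDataset(ds, seed = 43L)
  expect_false(identical(as.character(sequences(b1)),
                         as.character(sequences(b3))))
  # no rare species + no ambiguity codes: output identical to input
  clean <- toyBandDataset(sizes = c(11L, 12L), withAmbiguity = FALSE)
  expect_identical(as.character(sequences(balanceDataset(clean, seed = 1))),
                   as.character(sequences(clean)))
  # replicated copies of an ambiguity-free sequence are exact duplicates
  cleanRare <- toyBandDataset(sizes = 2L, withAmbiguity = FALSE)
  balRare <- balanceDataset(cleanRare, seed = 1)
  expect_identical(length(unique(as.character(sequences(balRare)))), 2L)
})

test_that("stratifiedSplit keeps every species in both parts at ~10%", {
  ds <- balanceDataset(toyBandDataset(sizes = c(1L, 2L, 5L, 10L, 20L, 40L)),
                       seed = 3L)
  sp <- stratifiedSplit(ds, 0.1, seed = 9L)
  expect_identical(sort(c(names(sp$train), names(sp$test))), sort(names(ds)))
  expect_length(intersect(names(sp$train), names(sp$test)), 0L)
  cntAll <- countPerSpecies(ds)
  cntTr <- countPerSpecies(sp$train)
  cntTe <- countPerSpecies(sp$test)
  expect_identical(sort(names(cntTr)), sort(names(cntAll)))
  expect_identical(sort(names(cntTe)), sort(names(cntAll)))
  for (s in names(cntAll)) {
    expect_lte(abs(cntTe[[s]] - 0.1 * cntAll[[s]]), 1)
  }
  # determinism and seed sensitivity with identical per-species counts
  sp2 <- stratifiedSplit(ds, 0.1, seed = 9L)
  expect_identical(names(sp2$test), names(sp$test))
  sp3 <- stratifiedSplit(ds, 0.1, seed = 10L)
  expect_false(identical(names(sp3$test), names(sp$test)))
  expect_identical(countPerSpecies(sp3$test), cntTe)
  # 10 records at fraction 0.1 -> 9 train / 1 test
  ds10 <- toyBandDataset(sizes = 10L, withAmbiguity = FALSE)
  s10 <- stratifiedSplit(ds10, 0.1, seed = 1L)
  expect_identical(c(length(s10$train), length(s10$test)), c(9L, 1L))
})

test_that("stratifiedSplit refuses singleton species with advice", {
  ds <- toyBandDataset(sizes = c(1L, 5L))
  expect_error(stratifiedSplit(ds, 0.1, seed = 1L), "balanceDataset")
})
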