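# Fixture builders shared across test files. Everything is generated in code.

rankRow <- function(genus, species) {
  c("Bacteria", "Phylum1", "Class1", "Order1", "Family1", genus, species)
}

# One species per requested size; sequences carry an ambiguity code so the
# resolution step is exercised.
toyBandDataset <- function(sizes = c(1L, 2L, 3L, 5L, 6L, 10L, 11L, 12L),
                           seqLength = 40L, withAmbiguity = TRUE) {
  ids <- character(0); seqs <- character(0); ranks <- NULL
  set.seed(424)
  for (i in seq_along(sizes)) {
    sp <- sprintf("Genus%d_sp1", i)
    for (j in seq_len(sizes[i])) {
      s <- paste(sample(c("A", "C", "G", "T"), seqLength, TRUE), collapse = "")
      if (withAmbiguity) {
        substr(s, 5L, 5L) <- "N"
        substr(s, 11L, 11L) <- "R"
      }
      ids <- c(ids, sprintf("sp%d_r%d", i, j))
      seqs <- c(seqs, s)
      ranks <- rbind(ranks, rankRow(sprintf("Genus%d", i), sp))
    }
  }
  makeDataset(ids, seqs, ranks)
}

randomIupacString <- function(n, ambProb = 0.1) {
  amb <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  paste(ifelse(runif(n) < ambProb, sample(amb, n, TRUE),
               sample(c("A", "C", "G", "T"), n, TRUE)), collapse = "")
}

writeFastaLines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

writeTaxLines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Small benchmark community used by several training tests.
benchCommunity <- function(nSpecies = 12L, reads = 20L, len = 200L,
                           divergence = 0.10, seed = 7L) {
  simulateCommunity(simConfig(nSpecies = nSpecies, speciesPerGenus = 4L,
                              seqLength = len, divergence = divergence,
                              withinRate = 0.005, ambiguityRate = 0.002,
                              readsPerSpecies = reads, seed = seed))
}
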