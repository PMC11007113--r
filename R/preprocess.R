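# Default abundance-based replication table: species holding 1-2 reads are
# brought to 12x their count, 3-5 reads to 4x, 6-10 reads to 2x; species with
# >= 11 reads are left at 1x (ambiguity resolution only).
defaultReplicationTable <- function() {
  list(list(counts = 1:2,  factor = 12L),
       list(counts = 3:5,  factor = 4L),
       list(counts = 6:10, factor = 2L))
}

#' Count reads per species
#'
#' @param ds an \linkS4class{AmpliconDataset}.
#' @return named integer vector, species -> number of records, in sorted
#'   species order.
#' @export
countPerSpecies <- function(ds) {
  if (length(ds) == 0L) stop("dataset is empty")
  sp <- speciesLabels(ds)
  tab <- table(sp[sp != ""])
  setNames(as.integer(tab), names(tab))
}

#' Replication factor for a species read count
#'
#' Total multiplier applied to every sequence of a species with \code{n}
#' reads: counts 1-2 map to 12, 3-5 to 4, 6-10 to 2, and species at or above
#' the high-abundance threshold (default 11) are not replicated. The factor
#' is a total multiplier, so a 2-read species ends up with 2 x 12 = 24 reads.
#'
#' @param n species read count (vectorized).
#' @param threshold high-abundance threshold; counts >= threshold get
#'   factor 1.
#' @param table replication table: list of \code{list(counts=, factor=)}
#'   entries whose count ranges must be disjoint and cover
#'   \code{1..(threshold-1)}.
#' @return integer factor(s).
#' @examples
#' replicationFactor(c(1, 2, 4, 8, 11, 500))  # 12 12 4 2 1 1
#' @export
replicationFactor <- function(n, threshold = 11L,
                              table = defaultReplicationTable()) {
  if (any(n <= 0)) stop("species read count must be >= 1")
  covered <- sort(unlist(lapply(table, `[[`, "counts")))
  if (anyDuplicated(covered) || !identical(covered, seq_len(threshold - 1L))) {
    stop("replication table ranges must be disjoint and cover 1..(threshold-1)")
  }
  lut <- integer(threshold - 1L)
  for (entry in table) lut[entry$counts] <- as.integer(entry$factor)
  ifelse(n >= threshold, 1L, lut[pmin(n, threshold - 1L)])
}

#' Randomly resolve IUPAC ambiguity codes to concrete bases
#'
#' Every ambiguity code (N, R, Y, S, W, K, M, B, D, H, V) is replaced by a
#' base drawn uniformly from that code's IUPAC set; A/C/G/T positions are
#' untouched and length is preserved. Draws come from R's current RNG
#' stream, so callers seed for reproducibility.
#'
#' @param seq a single IUPAC DNA string (uppercase).
#' @return the resolved A/C/G/T string.
#' @examples
#' set.seed(1); resolveAmbiguous("ARG")  # "AAG" or "AGG"
#' @export
resolveAmbiguous <- function(seq) {
  chars <- seqToChars(seq)
  idx <- match(chars, IUPAC_LETTERS)
  if (anyNA(idx)) {
    bad <- chars[which(is.na(idx))[1L]]
    stop(sprintf("non-IUPAC character '%s' in sequence", bad))
  }
  amb <- which(idx > 4L)
  if (length(amb)) {
    chars[amb] <- vapply(idx[amb], function(i) {
      s <- IUPAC_SETS[[i]]
      s[sample.int(length(s), 1L)]
    }, character(1))
  }
  charsToSeq(chars)
}

#' Balance a dataset by abundance-based replication and resolve ambiguities
#'
#' The two preprocessing steps applied to the classification database:
#' high-abundance species (read count >= \code{threshold}) keep each
#' sequence once with ambiguity codes randomly resolved; rare species are
#' replicated so each sequence appears \code{replicationFactor(n)} times in
#' total, every copy independently ambiguity-resolved (copies of
#' ambiguity-free sequences are exact duplicates). Replicated copies get ids
#' \code{id.rep1}, \code{id.rep2}, ... The output contains no ambiguity
#' codes. Per-record RNG streams are derived from \code{(seed, record id)},
#' so the result is invariant to record order.
#'
#' @param ds an \linkS4class{AmpliconDataset} labeled at species level.
#' @param threshold high-abundance threshold (default 11).
#' @param table replication table, see \code{\link{replicationFactor}}.
#' @param seed integer seed.
#' @return a new \linkS4class{AmpliconDataset} of size
#'   \code{sum(n_s * replicationFactor(n_s))}.
#' @export
balanceDataset <- function(ds, threshold = 11L,
                           table = defaultReplicationTable(), seed = 1L) {
  counts <- countPerSpecies(ds)
  sp <- speciesLabels(ds)
  fac <- replicationFactor(counts[sp], threshold = threshold, table = table)
  ids <- names(ds)
  seqs <- as.character(sequences(ds))
  outIds <- vector("list", length(ds))
  outSeqs <- vector("list", length(ds))
  rows <- rep.int(seq_along(ids), fac)
  for (i in seq_along(ids)) {
    f <- fac[i]
    copyIds <- if (f == 1L) ids[i] else {
      c(ids[i], paste0(ids[i], ".rep", seq_len(f - 1L)))
    }
    outIds[[i]] <- copyIds
    outSeqs[[i]] <- withSeed(deriveSeed(seed, ids[i]), {
      vapply(seq_len(f), function(j) resolveAmbiguous(seqs[i]), character(1))
    })
  }
  tx <- taxonomy(ds)[rows, , drop = FALSE]
  dss <- Biostrings::DNAStringSet(unlist(outSeqs, use.names = FALSE))
  names(dss) <- unlist(outIds, use.names = FALSE)
  new("AmpliconDataset", sequences = dss, taxonomy = tx,
      labelIndex = ds@labelIndex)
}

#' Stratified train/test split
#'
#' Splits a dataset so every species appears in both parts: the per-species
#' test share is \code{round(n * testFraction)} clamped to \code{[1, n-1]}.
#' Deterministic given the seed (per-species streams derived from
#' \code{(seed, species)}, so the partition is invariant to record order).
#'
#' @param ds an \linkS4class{AmpliconDataset}; every species needs >= 2
#'   records — run \code{\link{balanceDataset}} first, its factors guarantee
#'   this.
#' @param testFraction test proportion, default 0.10.
#' @param seed integer seed.
#' @return list with elements \code{train}, \code{test} (both
#'   \code{AmpliconDataset}) and \code{testFraction}.
#' @export
stratifiedSplit <- function(ds, testFraction = 0.10, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1)
  counts <- countPerSpecies(ds)
  if (any(counts < 2L)) {
    bad <- names(counts)[counts < 2L]
    stop(sprintf(paste0("species with a single record cannot be stratified ",
                        "(%s%s); run balanceDataset() first"),
                 paste(head(bad, 3L), collapse = ", "),
                 if (length(bad) > 3L) ", ..." else ""))
  }
  sp <- speciesLabels(ds)
  testSel <- logical(length(ds))
  for (s in names(counts)) {
    idx <- sort(which(sp == s))
    n <- length(idx)
    nTest <- min(max(as.integer(round(n * testFraction)), 1L), n - 1L)
    pick <- idx[withSeed(deriveSeed(seed, s), sample.int(n, nTest))]
    testSel[pick] <- TRUE
  }
  list(train = ds[!testSel], test = ds[testSel], testFraction = testFraction)
}
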