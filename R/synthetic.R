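# Synthetic SILVA-like communities: a taxonomy tree, divergent per-species
# reference sequences, long-tailed per-species read counts, and IUPAC
# ambiguity injection. Everything is a pure function of the SimConfig.

#' Configuration for the synthetic community generator
#'
#' Defaults emulate the classification database's stated character: long
#' sequences (1500 bp), high inter-sequence similarity (10\% divergence
#' between sister species, 0.5\% within-species read noise), sprinkled IUPAC
#' ambiguity codes, and a long-tailed species-abundance profile.
#'
#' @param nSpecies number of species (>= 2).
#' @param speciesPerGenus species per genus (genera are filled round-robin).
#' @param seqLength reference length in bases.
#' @param divergence expected pairwise difference fraction between sister
#'   species (the per-lineage mutation rate is calibrated so the expected
#'   sister-pair difference equals this value exactly).
#' @param withinRate per-base substitution rate of individual reads.
#' @param ambiguityRate per-base probability that a read base is replaced by
#'   a compatible IUPAC ambiguity code (one whose set contains the true
#'   base).
#' @param zipfExponent exponent of the truncated Zipf abundance profile
#'   (the default 2 gives the steep head and long tail typical of curated
#'   rRNA databases, and populates every replication band once the tail
#'   reaches the minimum count).
#' @param minCount,maxCount smallest/largest per-species read count.
#' @param readsPerSpecies optional fixed read count overriding the Zipf
#'   profile (used by balanced benchmarks).
#' @param seed integer seed; equal configs give byte-identical communities.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(nSpecies = 20L, speciesPerGenus = 4L,
                      seqLength = 1500L, divergence = 0.10,
                      withinRate = 0.005, ambiguityRate = 0.002,
                      zipfExponent = 2, minCount = 1L, maxCount = 600L,
                      readsPerSpecies = NULL, seed = 1L) {
  stopifnot(nSpecies >= 2L, seqLength >= 1L, divergence >= 0, divergence <= 0.6,
            withinRate >= 0, withinRate <= 1, ambiguityRate >= 0,
            ambiguityRate <= 1, minCount >= 1L)
  structure(list(nSpecies = as.integer(nSpecies),
                 speciesPerGenus = as.integer(speciesPerGenus),
                 seqLength = as.integer(seqLength), divergence = divergence,
                 withinRate = withinRate, ambiguityRate = ambiguityRate,
                 zipfExponent = zipfExponent, minCount = as.integer(minCount),
                 maxCount = as.integer(maxCount),
                 readsPerSpecies = readsPerSpecies,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Per-lineage substitution rate q such that two sister sequences, each
# mutated independently from their ancestor at rate q, differ at an expected
# fraction p of sites: p = 2q(1-q) + (2/3)q^2 (both-mutated sites agree with
# probability 1/3).
sisterRate <- function(p) {
  if (p <= 0) return(0)
  (2 - sqrt(4 - 16 * p / 3)) * 3 / 8
}

mutateSeq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(BASES, b), 1L)
    }, character(1))
  }
  chars
}

#' Simulate a seven-rank taxonomy
#'
#' Species are grouped into genera round-robin; higher ranks nest genera
#' (four genera per family, and so on up the tree). Species names are
#' unique.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return character matrix (nSpecies x 7) with columns domain..species.
#' @export
simulateTaxonomy <- function(cfg) {
  nG <- ceiling(cfg$nSpecies / cfg$speciesPerGenus)
  gOf <- rep(seq_len(nG), each = cfg$speciesPerGenus)[seq_len(cfg$nSpecies)]
  within <- stats::ave(gOf, gOf, FUN = seq_along)
  fam <- ceiling(gOf / 4); ord <- ceiling(fam / 4); cls <- ceiling(ord / 4)
  phy <- ceiling(cls / 4)
  m <- cbind(domain = "Bacteria",
             phylum = sprintf("Phylum%d", phy),
             class = sprintf("Class%d", cls),
             order = sprintf("Order%d", ord),
             family = sprintf("Family%d", fam),
             genus = sprintf("Genus%d", gOf),
             species = sprintf("Genus%d_sp%d", gOf, within))
  rownames(m) <- m[, "species"]
  m
}

#' Simulate divergent reference sequences along the taxonomy
#'
#' A random root sequence is mutated down the tree: one intermediate
#' ancestor per genus, then one reference per species. The per-lineage rate
#' is calibrated so sister species differ at an expected fraction
#' \code{divergence} of sites; genus ancestors diverge at twice that rate,
#' so cross-genus pairs are clearly more distant.
#'
#' @param tax taxonomy matrix from \code{\link{simulateTaxonomy}}.
#' @param cfg a \code{\link{simConfig}}.
#' @return named character vector, species -> reference sequence.
#' @export
simulateReferences <- function(tax, cfg) {
  withSeed(deriveSeed(cfg$seed, "references"), {
    root <- sample(BASES, cfg$seqLength, replace = TRUE)
    q <- sisterRate(cfg$divergence)
    genera <- unique(tax[, "genus"])
    genusRef <- lapply(genera, function(g) mutateSeq(root, 2 * q))
    names(genusRef) <- genera
    refs <- vapply(seq_len(nrow(tax)), function(i) {
      charsToSeq(mutateSeq(genusRef[[tax[i, "genus"]]], q))
    }, character(1))
    names(refs) <- tax[, "species"]
    refs
  })
}

#' Sample a long-tailed community of reads
#'
#' Per-species read counts follow a truncated Zipf profile (count of the
#' rank-i species is \code{maxCount * i^-zipfExponent}, clamped to
#' \code{minCount}), or the fixed \code{readsPerSpecies} when set. Each read
#' is its species reference with independent per-base substitutions at
#' \code{withinRate}, after which each base is replaced, with probability
#' \code{ambiguityRate}, by an IUPAC ambiguity code drawn uniformly from the
#' codes compatible with (containing) the true base.
#'
#' @param refs references from \code{\link{simulateReferences}}.
#' @param tax taxonomy matrix from \code{\link{simulateTaxonomy}}.
#' @param cfg a \code{\link{simConfig}}.
#' @return an \linkS4class{AmpliconDataset}.
#' @export
sampleReads <- function(refs, tax, cfg) {
  nS <- nrow(tax)
  counts <- if (!is.null(cfg$readsPerSpecies)) {
    rep(as.integer(cfg$readsPerSpecies), nS)
  } else {
    pmax(cfg$minCount,
         as.integer(round(cfg$maxCount * seq_len(nS)^(-cfg$zipfExponent))))
  }
  compat <- lapply(setNames(BASES, BASES), function(b) {
    AMBIGUITY_LETTERS[vapply(AMBIGUITY_LETTERS,
                             function(a) b %in% IUPAC_SETS[[a]], logical(1))]
  })
  ids <- character(0); seqs <- character(0); rows <- integer(0)
  for (i in seq_len(nS)) {
    sp <- tax[i, "species"]
    reads <- withSeed(deriveSeed(cfg$seed, paste0("reads-", sp)), {
      vapply(seq_len(counts[i]), function(j) {
        chars <- mutateSeq(seqToChars(refs[[sp]]), cfg$withinRate)
        if (cfg$ambiguityRate > 0) {
          hit <- which(runif(length(chars)) < cfg$ambiguityRate)
          if (length(hit)) {
            chars[hit] <- vapply(chars[hit], function(b) {
              cset <- compat[[b]]
              cset[sample.int(length(cset), 1L)]
            }, character(1))
          }
        }
        charsToSeq(chars)
      }, character(1))
    })
    ids <- c(ids, sprintf("%s_read%d", sp, seq_len(counts[i])))
    seqs <- c(seqs, reads)
    rows <- c(rows, rep.int(i, counts[i]))
  }
  makeDataset(ids, seqs, tax[rows, , drop = FALSE])
}

#' Generate a complete synthetic community
#'
#' Convenience wrapper: taxonomy, references and reads from one config.
#' Fully deterministic — equal configs give byte-identical datasets.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{dataset} (\linkS4class{AmpliconDataset}),
#'   \code{taxonomy}, \code{references} and \code{counts} (truth manifest).
#' @export
simulateCommunity <- function(cfg = simConfig()) {
  tax <- simulateTaxonomy(cfg)
  refs <- simulateReferences(tax, cfg)
  ds <- sampleReads(refs, tax, cfg)
  list(dataset = ds, taxonomy = tax, references = refs,
       counts = countPerSpecies(ds))
}
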