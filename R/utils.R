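# IUPAC nucleotide ambiguity sets (DNA, U already normalized to T upstream).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)
AMBIGUITY_LETTERS <- setdiff(IUPAC_LETTERS, c("A", "C", "G", "T"))
BASES <- c("A", "C", "G", "T")

RANK_NAMES <- c("domain", "phylum", "class", "order", "family",
                "genus", "species")

# Fixed special-token ids (0-based): [PAD]=0, [UNK]=1, [CLS]=2, [SEP]=3,
# [MASK]=4. k-mer tokens follow in lexicographic order.
SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Derive a reproducible sub-seed from a base seed and a string key
#'
#' Polynomial string hash folded into the 31-bit range so per-species RNG
#' streams depend only on (seed, key), never on record order.
#'
#' @param seed integer base seed.
#' @param key character scalar.
#' @return integer in [0, 2^31-2].
#' @keywords internal
deriveSeed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (v in utf8ToInt(as.character(key))) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Split a character vector of sequences into per-position letter matrices is
# avoided; instead use strsplit on demand.
seqToChars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

charsToSeq <- function(x) paste0(x, collapse = "")
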