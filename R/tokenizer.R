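#' Split a sequence into overlapping k-mer tokens
#'
#' Sliding window of width k, stride 1, left to right, so a sequence of
#' length L yields max(0, L - k + 1) tokens. Ambiguity codes are kept in the
#' tokens here; they map to \code{[UNK]} at encoding time.
#'
#' @param seq a single IUPAC DNA string.
#' @param k k-mer length (>= 1).
#' @return character vector of k-mers (empty, with a warning, when L < k).
#' @examples
#' kmerize("ATGCA", 3)  # "ATG" "TGC" "GCA"
#' @export
kmerize <- function(seq, k = 3L) {
  stopifnot(length(seq) == 1L, k >= 1L)
  L <- nchar(seq)
  if (L < k) {
    warning(sprintf("sequence length %d < k = %d: no tokens", L, k))
    return(character(0))
  }
  substring(seq, seq_len(L - k + 1L), k:L)
}

#' Build the k-mer vocabulary
#'
#' All 4^k DNA k-mers in lexicographic order preceded by the five special
#' tokens; ids are 0-based with \code{[PAD]}=0, \code{[UNK]}=1,
#' \code{[CLS]}=2, \code{[SEP]}=3, \code{[MASK]}=4. Built deterministically:
#' two calls with the same k give identical id assignments.
#'
#' @param k k-mer length, 1..8 (memory guard: 4^8 + 5 tokens).
#' @return a \linkS4class{KmerVocabulary} of size 4^k + 5.
#' @examples
#' length(buildVocab(3))  # 69
#' @export
buildVocab <- function(k = 3L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 8L) stop("k must be in 1..8")
  kmers <- do.call(paste0, expand.grid(rep(list(BASES), k),
                                       stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  new("KmerVocabulary", k = k, tokens = c(SPECIAL_TOKENS, sort(kmers)))
}

vocabId <- function(vocab, token) match(token, vocab@tokens) - 1L

#' Encode k-mer tokens as vocabulary ids
#'
#' Tokens containing any non-ACGT symbol (or otherwise absent from the
#' vocabulary) map to \code{[UNK]}. With \code{addSpecials}, \code{[CLS]} is
#' prepended and \code{[SEP]} appended.
#'
#' @param tokens character vector of k-mers (from \code{\link{kmerize}}).
#' @param vocab a \linkS4class{KmerVocabulary} with matching k.
#' @param addSpecials prepend \code{[CLS]} / append \code{[SEP]}.
#' @return integer vector of 0-based token ids.
#' @export
encodeTokens <- function(tokens, vocab, addSpecials = FALSE) {
  if (length(tokens) && any(nchar(tokens) != vocab@k)) {
    stop("token length does not match vocabulary k")
  }
  ids <- match(tokens, vocab@tokens) - 1L
  ids[is.na(ids)] <- 1L  # [UNK]
  if (addSpecials) ids <- c(2L, ids, 3L)  # [CLS] ... [SEP]
  ids
}

#' Decode vocabulary ids back to tokens
#' @param ids integer vector of 0-based ids.
#' @param vocab a \linkS4class{KmerVocabulary}.
#' @return character vector of tokens.
#' @export
decodeTokens <- function(ids, vocab) {
  if (any(ids < 0L | ids >= length(vocab@tokens))) stop("id out of range")
  vocab@tokens[ids + 1L]
}

#' Tokenize and encode a whole sequence in one step
#' @inheritParams kmerize
#' @inheritParams encodeTokens
#' @return integer vector of 0-based content token ids.
#' @export
encodeSequence <- function(seq, vocab, addSpecials = FALSE) {
  encodeTokens(kmerize(seq, vocab@k), vocab, addSpecials = addSpecials)
}

#' Chunk a token-id stream into encoder-sized windows
#'
#' Transformer encoders cap input length (512 tokens for the BERT family)
#' while a full-length 16S gene yields ~1498 k-mer tokens, so content ids
#' are cut into consecutive windows of at most \code{maxTokens - 2} ids
#' (leaving room for \code{[CLS]}/\code{[SEP]}), successive windows sharing
#' \code{overlap} ids. \code{\link{reassembleWindows}} inverts the chunking.
#'
#' @param ids integer vector of content token ids (no specials).
#' @param maxTokens window capacity including the two specials (default 512).
#' @param overlap ids shared by successive windows (< maxTokens - 2).
#' @return list of integer vectors covering \code{ids} in order.
#' @examples
#' lengths(chunkWindows(1:10, maxTokens = 6, overlap = 0))  # 4 4 2
#' @export
chunkWindows <- function(ids, maxTokens = 512L, overlap = 64L) {
  cap <- as.integer(maxTokens) - 2L
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= cap) stop("overlap must be in [0, maxTokens - 3]")
  n <- length(ids)
  if (n <= cap) return(list(ids))
  step <- cap - overlap
  starts <- seq.int(1L, n - overlap, by = step)
  # drop a final start that would only re-emit already-covered ids
  starts <- starts[starts == 1L | starts + overlap <= n]
  lapply(starts, function(s) ids[s:min(s + cap - 1L, n)])
}

#' Reassemble chunked windows into the original stream
#'
#' Inverse of \code{\link{chunkWindows}}: the first window is kept whole and
#' each later window contributes everything after its first \code{overlap}
#' entries. Works for id vectors and for embedding-row matrices; for
#' matrices the \code{overlap} duplicated rows are averaged between the two
#' windows that share them.
#'
#' @param windows list of integer vectors or of numeric matrices (rows =
#'   tokens).
#' @param overlap the overlap the windows were built with.
#' @return an integer vector or numeric matrix matching the original input.
#' @export
reassembleWindows <- function(windows, overlap = 64L) {
  overlap <- as.integer(overlap)
  if (length(windows) == 1L) return(windows[[1L]])
  if (is.matrix(windows[[1L]])) {
    out <- windows[[1L]]
    for (w in windows[-1L]) {
      if (overlap > 0L) {
        n <- nrow(out)
        shared <- (n - overlap + 1L):n
        out[shared, ] <- (out[shared, , drop = FALSE] +
                          w[seq_len(overlap), , drop = FALSE]) / 2
        out <- rbind(out, w[-seq_len(overlap), , drop = FALSE])
      } else {
        out <- rbind(out, w)
      }
    }
    out
  } else {
    out <- windows[[1L]]
    for (w in windows[-1L]) {
      out <- c(out, if (overlap > 0L) w[-seq_len(overlap)] else w)
    }
    out
  }
}
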