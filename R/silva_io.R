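#' Read a FASTA file of 16S rRNA gene sequences
#'
#' Parses standard (possibly multi-line) FASTA. Sequences are uppercased and
#' RNA \code{U} is normalized to DNA \code{T} at read time so every
#' downstream k-mer token is over the DNA alphabet; SILVA distributes rRNA
#' sequences with \code{U}. Any character outside the 15-letter IUPAC
#' nucleotide alphabet is a parse error reported with its line number.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}; names are the Feature IDs (header
#'   text up to the first whitespace), order as in the file.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgu", ">b", "ACGT"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  isHdr <- startsWith(lines, ">")
  if (!isHdr[1L]) {
    stop(sprintf("malformed FASTA: line %d does not start a record", lineNo[1L]))
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[isHdr]))
  if (any(ids == "")) {
    bad <- lineNo[isHdr][which(ids == "")[1L]]
    stop(sprintf("malformed FASTA header at line %d: empty id", bad))
  }
  rec <- cumsum(isHdr)
  seqLines <- toupper(lines[!isHdr])
  badChar <- grepl(sprintf("[^%s]", paste(c(IUPAC_LETTERS, "U"), collapse = "")),
                   seqLines)
  if (any(badChar)) {
    bad <- lineNo[!isHdr][which(badChar)[1L]]
    stop(sprintf("illegal sequence character at line %d (not an IUPAC nucleotide code)",
                 bad))
  }
  seqs <- vapply(split(seqLines, factor(rec[!isHdr], levels = seq_along(ids))),
                 paste0, character(1), collapse = "")
  if (any(seqs == "" | is.na(seqs))) {
    bad <- which(seqs == "" | is.na(seqs))[1L]
    stop(sprintf("record '%s' has no sequence lines", ids[bad]))
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  out <- Biostrings::DNAStringSet(unname(seqs))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' Mirrors \code{\link{readFasta}} bit-exactly after normalization:
#' \code{readFasta(writeFasta(x))} is the identity on normalized records.
#'
#' @param x a named \code{DNAStringSet} or \code{AmpliconDataset}.
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is(x, "AmpliconDataset")) x <- sequences(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Parse a SILVA-style taxonomy table
#'
#' Reads a two-column delimited file (Feature ID, 7-rank lineage string of
#' the form \code{d__Bacteria; p__...; s__...}). Rank prefixes (\code{x__})
#' are stripped, whitespace around ranks is trimmed, and missing trailing
#' ranks are filled with empty strings. Both the \code{"; "} and \code{";"}
#' dialects are accepted. A header row naming the first column
#' \code{Feature ID} (QIIME 2 export convention) is skipped automatically.
#'
#' @param path path to the taxonomy file.
#' @param sep field separator, default tab.
#' @return named list of character(7) rank vectors, names are Feature IDs.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("id1\td__Bacteria; p__P; c__C; o__O; f__F; g__G; s__G_sp1", f)
#' parseTaxonomy(f)[["id1"]]
#' @export
parseTaxonomy <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tab <- read.delim(path, sep = sep, header = FALSE, quote = "",
                    colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2L) stop("taxonomy file must have two columns")
  if (nrow(tab) && tolower(gsub("[ _]", "", tab[1L, 1L])) %in%
      c("featureid", "otuid", "id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("taxonomy file has no data rows")
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate Feature ID in taxonomy: ", paste(unique(dup), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    ranks <- strsplit(tab[i, 2L], ";", fixed = TRUE)[[1L]]
    ranks <- trimws(ranks)
    ranks <- sub("^[a-zA-Z]__", "", ranks)
    if (length(ranks) > 7L) {
      stop(sprintf("Feature ID '%s' has %d ranks (max 7)", ids[i], length(ranks)))
    }
    r <- c(ranks, rep("", 7L - length(ranks)))
    names(r) <- RANK_NAMES
    r
  })
  names(out) <- ids
  out
}

#' Format a 7-rank vector back into the SILVA lineage string
#' @param ranks character(7) in domain..species order.
#' @return a single \code{d__...; s__...} string (empty trailing ranks kept,
#'   so writing then parsing round-trips).
#' @export
formatTaxonomy <- function(ranks) {
  paste(paste0(c("d", "p", "c", "o", "f", "g", "s"), "__", ranks),
        collapse = "; ")
}

#' Write a taxonomy table in the two-column SILVA format
#' @param x an \code{AmpliconDataset}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTaxonomy <- function(x, path) {
  tx <- taxonomy(x)
  lineage <- vapply(seq_len(nrow(tx)), function(i) {
    formatTaxonomy(as.character(as.data.frame(tx[i, ]))[seq_len(7L)])
  }, character(1))
  writeLines(paste(names(x), lineage, sep = "\t"), path)
  invisible(path)
}

#' Join sequences with taxonomy into a labeled dataset
#'
#' Inner join on Feature ID. Records lacking taxonomy — or lacking a
#' non-empty species label unless \code{keepUnlabeled} — are dropped with a
#' message stating the count. Label ids are assigned contiguously from 0 in
#' sorted species order.
#'
#' @param seqs named \code{DNAStringSet} from \code{\link{readFasta}}.
#' @param tax id-to-ranks map from \code{\link{parseTaxonomy}}.
#' @param keepUnlabeled keep records whose species rank is empty (for
#'   genus-level-only runs). Default drops them: species is the
#'   classification target.
#' @return an \linkS4class{AmpliconDataset}.
#' @export
joinDataset <- function(seqs, tax, keepUnlabeled = FALSE) {
  ids <- names(seqs)
  hit <- ids %in% names(tax)
  dropped <- sum(!hit)
  keep <- ids[hit]
  ranks <- do.call(rbind, tax[keep])
  if (length(keep) && !keepUnlabeled) {
    unl <- ranks[, "species"] == ""
    dropped <- dropped + sum(unl)
    keep <- keep[!unl]
    ranks <- ranks[!unl, , drop = FALSE]
  }
  if (length(keep) == 0L) {
    stop("no records survive the sequence/taxonomy join")
  }
  if (dropped > 0L) {
    message(sprintf("joinDataset: dropped %d record(s) without usable taxonomy",
                    dropped))
  }
  sp <- ranks[, "species"]
  labelIndex <- sort(unique(sp[sp != ""]))
  new("AmpliconDataset",
      sequences = seqs[keep],
      taxonomy = S4Vectors::DataFrame(as.data.frame(ranks,
                                                    stringsAsFactors = FALSE),
                                      row.names = NULL),
      labelIndex = labelIndex)
}

#' Assemble an AmpliconDataset directly from in-memory pieces
#'
#' Convenience constructor used by the simulator and tests.
#'
#' @param ids character record ids.
#' @param seqs character sequences (IUPAC DNA).
#' @param ranksMatrix character matrix (n x 7) of taxonomy ranks.
#' @return an \linkS4class{AmpliconDataset}.
#' @export
makeDataset <- function(ids, seqs, ranksMatrix) {
  colnames(ranksMatrix) <- RANK_NAMES
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  sp <- ranksMatrix[, "species"]
  new("AmpliconDataset",
      sequences = dss,
      taxonomy = S4Vectors::DataFrame(as.data.frame(ranksMatrix,
                                                    stringsAsFactors = FALSE),
                                      row.names = NULL),
      labelIndex = sort(unique(sp[sp != ""])))
}
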