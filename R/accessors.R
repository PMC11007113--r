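#' @rdname AmpliconDataset-class
#' @export
setMethod("sequences", "AmpliconDataset", function(x) x@sequences)

#' @rdname AmpliconDataset-class
#' @export
setMethod("taxonomy", "AmpliconDataset", function(x) x@taxonomy)

#' @rdname AmpliconDataset-class
#' @export
setMethod("labelIndex", "AmpliconDataset", function(x) {
  data.frame(species = x@labelIndex,
             label = seq_along(x@labelIndex) - 1L)
})

#' @rdname AmpliconDataset-class
#' @export
setMethod("speciesLabels", "AmpliconDataset", function(x) x@taxonomy$species)

#' @rdname AmpliconDataset-class
#' @export
setMethod("labelIds", "AmpliconDataset", function(x) {
  match(x@taxonomy$species, x@labelIndex) - 1L
})

#' @rdname AmpliconDataset-class
#' @export
setMethod("length", "AmpliconDataset", function(x) length(x@sequences))

#' @rdname AmpliconDataset-class
#' @export
setMethod("names", "AmpliconDataset", function(x) names(x@sequences))

#' @rdname AmpliconDataset-class
#' @param i index (integer, logical or record id character).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "AmpliconDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  initialize(x,
    sequences = x@sequences[i],
    taxonomy = x@taxonomy[i, , drop = FALSE],
    labelIndex = x@labelIndex)
})

setMethod("show", "AmpliconDataset", function(object) {
  cat(sprintf("AmpliconDataset with %d records, %d species\n",
              length(object), length(object@labelIndex)))
  if (length(object)) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  sequence length: %d..%d\n", min(w), max(w)))
    n <- min(3L, length(object))
    sp <- object@taxonomy$species[seq_len(n)]
    cat(sprintf("  %s: %s\n", names(object)[seq_len(n)], sp), sep = "")
    if (length(object) > n) cat("  ...\n")
  }
})

#' @rdname KmerVocabulary-class
#' @param x,object a \code{KmerVocabulary}.
#' @export
setMethod("length", "KmerVocabulary", function(x) length(x@tokens))

setMethod("show", "KmerVocabulary", function(object) {
  cat(sprintf("KmerVocabulary: k = %d, %d tokens (4^k + 5 specials)\n",
              object@k, length(object@tokens)))
})

#' @rdname KmerEmbedder-class
#' @export
setMethod("embedderFingerprint", "HashEmbedder", function(x) {
  sprintf("hash/k=%d/d=%d/seed=%d", x@vocab@k, x@dModel, x@seed)
})

#' @rdname KmerEmbedder-class
#' @export
setMethod("embedderFingerprint", "TableEmbedder", function(x) {
  sprintf("table/k=%d/d=%d/sum=%.6g", x@vocab@k, x@dModel, sum(x@table))
})

#' @rdname KmerEmbedder-class
#' @export
setMethod("embedderFingerprint", "MLMEmbedder", function(x) {
  sprintf("mlm/k=%d/d=%d/layers=%d", x@vocab@k, x@dModel,
          x@config$nLayers)
})

setMethod("show", "HashEmbedder", function(object) {
  cat(sprintf("HashEmbedder: %s\n", embedderFingerprint(object)))
})
setMethod("show", "TableEmbedder", function(object) {
  cat(sprintf("TableEmbedder: %s\n", embedderFingerprint(object)))
})
setMethod("show", "MLMEmbedder", function(object) {
  cat(sprintf("MLMEmbedder: %s, trained %d epochs (final MLM loss %.4f)\n",
              embedderFingerprint(object), length(object@history),
              if (length(object@history)) tail(object@history, 1) else NA))
})

setMethod("show", "DSNetaxConfig", function(object) {
  cat(sprintf("DSNetaxConfig variant=%s\n", object@variant))
  cat(sprintf("  deep: stages [%s] blocks, widths [%s], radix %d, cardinality %d\n",
              paste(object@stageBlocks, collapse = ","),
              paste(object@stageWidths, collapse = ","),
              object@radix, object@cardinality))
  cat(sprintf("  shallow: %d Conv+ReLU layers, width %d; fusion %s; %d classes\n",
              object@shallowLayers, object@shallowWidth, object@fusion,
              object@nClasses))
})

setMethod("show", "DSNetaxModel", function(object) {
  d <- describeModel(object)
  cat(sprintf("DSNetaxModel (%s): %d conv layers, %d Split-Attention blocks, %d parameters\n",
              object@config@variant, d$convLayers, d$splitAttentionBlocks,
              d$nParameters))
  cat(sprintf("  classes: %d; embedder: %s\n", object@config@nClasses,
              object@embedderFingerprint))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport on %d records\n", object@n))
  for (k in names(object@topk)) {
    cat(sprintf("  species top-%s: %.2f%%", k, object@topk[[k]]))
    if (k %in% names(object@genusTopk)) {
      cat(sprintf("  (genus top-%s: %.2f%%)", k, object@genusTopk[[k]]))
    }
    cat("\n")
  }
})

setMethod("show", "HeadTailReport", function(object) {
  cat(sprintf("HeadTailReport at cutpoints %s\n",
              paste(object@cutpoints, collapse = ", ")))
  print(object@table, row.names = FALSE)
})
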