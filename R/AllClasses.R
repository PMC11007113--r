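#' AmpliconDataset: labeled 16S rRNA sequences
#'
#' Container coupling a \linkS4class{DNAStringSet} of 16S rRNA gene sequences
#' (names are the Feature IDs) with a seven-rank taxonomy table and a species
#' label index. Label ids are contiguous integers starting at 0, assigned in
#' sorted species-name order.
#'
#' @slot sequences \code{DNAStringSet}, one entry per record; names are
#'   unique Feature IDs.
#' @slot taxonomy \code{DataFrame} with columns \code{domain}, \code{phylum},
#'   \code{class}, \code{order}, \code{family}, \code{genus}, \code{species};
#'   one row per record, aligned with \code{sequences}.
#' @slot labelIndex character vector of species names; the label id of
#'   species \code{s} is \code{match(s, labelIndex) - 1L}.
#'
#' @exportClass AmpliconDataset
setClass("AmpliconDataset",
  representation(
    sequences  = "DNAStringSet",
    taxonomy   = "DataFrame",
    labelIndex = "character"
  )
)

setValidity("AmpliconDataset", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    msg <- c(msg, "all records must have non-empty ids")
  } else if (anyDuplicated(ids)) {
    msg <- c(msg, "record ids must be unique")
  }
  if (length(object@sequences) > 0 &&
      any(Biostrings::width(object@sequences) == 0L)) {
    msg <- c(msg, "sequences must be non-empty")
  }
  if (!identical(colnames(object@taxonomy), RANK_NAMES)) {
    msg <- c(msg, sprintf("taxonomy must have columns %s",
                          paste(RANK_NAMES, collapse = ", ")))
  }
  if (nrow(object@taxonomy) != length(object@sequences)) {
    msg <- c(msg, "taxonomy rows must align with sequences")
  }
  if (anyDuplicated(object@labelIndex)) {
    msg <- c(msg, "labelIndex species must be unique")
  }
  if (identical(colnames(object@taxonomy), RANK_NAMES) &&
      nrow(object@taxonomy) == length(object@sequences)) {
    sp <- object@taxonomy$species
    lab <- sp[!is.na(sp) & sp != ""]
    if (!all(lab %in% object@labelIndex)) {
      msg <- c(msg, "every non-empty species label must be in labelIndex")
    }
  }
  if (length(msg)) msg else TRUE
})

#' KmerVocabulary: token/id bijection over DNA k-mers
#'
#' All 4^k DNA k-mers in lexicographic order, preceded by the five special
#' tokens \code{[PAD]}, \code{[UNK]}, \code{[CLS]}, \code{[SEP]},
#' \code{[MASK]} whose ids are fixed at 0..4. Ids are 0-based.
#'
#' @slot k integer k-mer length.
#' @slot tokens character vector of length 4^k + 5; the id of
#'   \code{tokens[i]} is \code{i - 1}.
#'
#' @exportClass KmerVocabulary
setClass("KmerVocabulary",
  representation(k = "integer", tokens = "character")
)

setValidity("KmerVocabulary", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L) {
    msg <- c(msg, "k must be a positive integer")
  } else {
    if (length(object@tokens) != 4^object@k + 5L) {
      msg <- c(msg, "vocabulary size must be 4^k + 5")
    }
    if (!identical(object@tokens[seq_len(5L)], SPECIAL_TOKENS)) {
      msg <- c(msg, "first five tokens must be the fixed special tokens")
    }
    if (anyDuplicated(object@tokens)) {
      msg <- c(msg, "tokens must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' KmerEmbedder: providers of per-token word vectors
#'
#' Virtual parent of the three embedding providers: \code{HashEmbedder}
#' (deterministic random-table stub for tests), \code{TableEmbedder}
#' (imported token-to-vector table, e.g. exported from an external DNABERT
#' checkpoint) and \code{MLMEmbedder} (transformer encoder trained in this
#' package with the masked-language-model objective).
#'
#' @slot vocab the \linkS4class{KmerVocabulary} the provider is bound to.
#' @slot dModel integer embedding width.
#'
#' @exportClass KmerEmbedder
setClass("KmerEmbedder",
  representation("VIRTUAL", vocab = "KmerVocabulary", dModel = "integer")
)

#' @rdname KmerEmbedder-class
#' @slot table numeric matrix (vocabulary size x dModel) of token vectors.
#' @slot seed integer seed the table was drawn from.
#' @exportClass HashEmbedder
setClass("HashEmbedder",
  contains = "KmerEmbedder",
  representation(table = "matrix", seed = "integer")
)

#' @rdname KmerEmbedder-class
#' @exportClass TableEmbedder
setClass("TableEmbedder",
  contains = "KmerEmbedder",
  representation(table = "matrix")
)

#' @rdname KmerEmbedder-class
#' @slot params list of transformer weights.
#' @slot config list of architecture/training settings.
#' @slot history numeric vector of per-epoch MLM training loss.
#' @exportClass MLMEmbedder
setClass("MLMEmbedder",
  contains = "KmerEmbedder",
  representation(params = "list", config = "list", history = "numeric")
)

setValidity("KmerEmbedder", function(object) {
  if (length(object@dModel) != 1L || object@dModel < 1L) {
    "dModel must be a positive integer"
  } else TRUE
})

#' DSNetaxConfig: classifier architecture hyperparameters
#'
#' Architecture description for the deep-shallow parallel classifier and its
#' ablation variants. The default deep branch has four stages with 2, 3, 2
#' and 2 Split-Attention blocks; the default shallow branch is 3 Conv+ReLU
#' layers; pooled branch vectors are fused by concatenation.
#'
#' @slot variant one of \code{"cnn3"} (plain 3-layer CNN baseline),
#'   \code{"resnet34"} (plain residual baseline, stages 3,4,6,3),
#'   \code{"resnest"} (Split-Attention deep branch only) or
#'   \code{"dsnetax"} (deep + shallow fusion).
#' @slot stageBlocks integer block counts per deep stage.
#' @slot stageWidths integer channel widths per deep stage.
#' @slot stemWidth integer channels of the stem convolution.
#' @slot shallowLayers integer number of Conv+ReLU pairs (3, 4 or 5).
#' @slot shallowWidth integer channels of the shallow branch.
#' @slot radix integer splits per cardinal group in Split-Attention.
#' @slot cardinality integer number of cardinal groups.
#' @slot reduction integer bottleneck factor of the attention MLP.
#' @slot nClasses integer number of species labels.
#' @slot fusion \code{"concat"}, \code{"sum"} or \code{"gated"}.
#'
#' @exportClass DSNetaxConfig
setClass("DSNetaxConfig",
  representation(
    variant = "character",
    stageBlocks = "integer",
    stageWidths = "integer",
    stemWidth = "integer",
    shallowLayers = "integer",
    shallowWidth = "integer",
    radix = "integer",
    cardinality = "integer",
    reduction = "integer",
    nClasses = "integer",
    fusion = "character"
  )
)

setValidity("DSNetaxConfig", function(object) {
  msg <- character()
  if (!object@variant %in% c("cnn3", "resnet34", "resnest", "dsnetax")) {
    msg <- c(msg, "variant must be cnn3, resnet34, resnest or dsnetax")
  }
  if (length(object@stageBlocks) != 4L || any(object@stageBlocks < 1L)) {
    msg <- c(msg, "stageBlocks must be four positive counts")
  }
  if (length(object@stageWidths) != length(object@stageBlocks)) {
    msg <- c(msg, "stageWidths must match stageBlocks")
  }
  if (!object@shallowLayers %in% 3:5) {
    msg <- c(msg, "shallowLayers must be 3, 4 or 5")
  }
  if (object@radix < 1L || object@cardinality < 1L) {
    msg <- c(msg, "radix and cardinality must be >= 1")
  }
  if (any(object@stageWidths %% (object@radix * object@cardinality) != 0L)) {
    msg <- c(msg, "stage widths must be divisible by radix * cardinality")
  }
  if (any(object@stageWidths %/% object@reduction < object@cardinality)) {
    msg <- c(msg, "reduction too large for the stage widths")
  }
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (!object@fusion %in% c("concat", "sum", "gated")) {
    msg <- c(msg, "fusion must be concat, sum or gated")
  }
  if (length(msg)) msg else TRUE
})

#' DSNetaxModel: a built (possibly trained) classifier
#'
#' @slot config the \linkS4class{DSNetaxConfig} the network was built from.
#' @slot params list of weight tensors, keyed by layer name.
#' @slot labelIndex character vector mapping label id (position - 1) to
#'   species name.
#' @slot embedderFingerprint character fingerprint of the embedding provider
#'   the model was trained with; prediction refuses a mismatched provider.
#'
#' @exportClass DSNetaxModel
setClass("DSNetaxModel",
  representation(
    config = "DSNetaxConfig",
    params = "list",
    labelIndex = "character",
    embedderFingerprint = "character"
  )
)

#' EvalReport: top-k accuracies of a model on a test set
#'
#' @slot topk named numeric, percentage accuracy per k (names are k values).
#' @slot genusTopk named numeric, genus-level percentage accuracy per k
#'   (predicted species mapped to its genus).
#' @slot n integer number of test records scored.
#' @slot hits integer matrix (records x length(ks)) of 0/1 top-k hits, used
#'   for exact head/tail recombination.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(topk = "numeric", genusTopk = "numeric", n = "integer",
                 hits = "matrix")
)

#' HeadTailReport: long-tail evaluation at read-count cutpoints
#'
#' For each cutpoint c, the test set is split into HEAD (species whose
#' TRAINING read count is >= c) and TAIL (< c) and top-k accuracy is
#' computed per part. Empty parts are flagged as not reported rather than
#' scored 0.
#'
#' @slot cutpoints integer cutpoints used.
#' @slot table data.frame with columns cutpoint, part, n, and one accuracy
#'   column per k (NA when the part is empty).
#'
#' @exportClass HeadTailReport
setClass("HeadTailReport",
  representation(cutpoints = "integer", table = "data.frame")
)
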