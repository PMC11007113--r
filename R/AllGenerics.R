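#' @rdname AmpliconDataset-class
#' @param object,x an \code{AmpliconDataset}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname AmpliconDataset-class
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname AmpliconDataset-class
#' @export
setGeneric("labelIndex", function(x) standardGeneric("labelIndex"))

#' @rdname AmpliconDataset-class
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname AmpliconDataset-class
#' @export
setGeneric("labelIds", function(x) standardGeneric("labelIds"))

#' @rdname KmerEmbedder-class
#' @param x an embedding provider.
#' @export
setGeneric("embedderFingerprint",
           function(x) standardGeneric("embedderFingerprint"))

#' Embed an encoded token-id sequence into a per-token vector matrix
#'
#' @param provider a \linkS4class{KmerEmbedder}.
#' @param ids integer vector of 0-based content token ids (no specials).
#' @param ... provider-specific arguments such as \code{maxTokens} and
#'   \code{overlap} window controls.
#' @return numeric matrix, one row per content token, \code{dModel} columns.
#' @export
setGeneric("embedIds", function(provider, ids, ...) standardGeneric("embedIds"))
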