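#' @importClassesFrom Biostrings BStringSet XStringSet
#' @importFrom Biostrings BStringSet DNAStringSet readDNAStringSet
#' @importFrom BiocGenerics width
#' @importFrom S4Vectors isSingleString
NULL

#' Construct a BarcodeSeqSet
#'
#' @param sequences Character vector or [Biostrings::XStringSet] of barcode
#'   sequences (may contain IUPAC codes and \code{-}) or printable encoded
#'   token streams.
#' @param labels Integer vector of class labels, one per sequence.
#' @param labelTable Label table \code{data.frame} (columns \code{order},
#'   \code{label}); defaults to an anonymous table spanning the labels seen.
#' @param ids Optional character identifiers; defaults to existing names or
#'   \code{seq_1, seq_2, ...}.
#' @return A [BarcodeSeqSet-class] object.
#' @examples
#' bs <- BarcodeSeqSet(c("ACGTACG", "TTGCA-A"), c(1L, 2L))
#' length(bs)
#' @export
BarcodeSeqSet <- function(sequences, labels, labelTable = NULL, ids = NULL) {
  sequences <- BStringSet(sequences)
  labels <- as.integer(labels)
  if (is.null(ids)) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(sequences))
  }
  names(sequences) <- ids
  if (is.null(labelTable)) {
    C <- if (length(labels)) max(labels) else 0L
    labelTable <- data.frame(order = sprintf("class_%d", seq_len(C)),
                             label = seq_len(C))
  }
  new("BarcodeSeqSet", sequences = sequences, labels = labels,
      labelTable = labelTable)
}

#' Accessor generics for barcode sets and dictionaries
#'
#' \code{barcodeSequences} returns the underlying \code{DNAStringSet};
#' \code{seqLabels} the integer label vector; \code{labelTable} the
#' order-name to label mapping.
#'
#' @param x A [BarcodeSeqSet-class].
#' @return See the individual descriptions.
#' @name barcode-accessors
#' @aliases barcodeSequences seqLabels labelTable
#' @export
setGeneric("barcodeSequences", function(x) standardGeneric("barcodeSequences"))

#' @rdname barcode-accessors
#' @export
setGeneric("seqLabels", function(x) standardGeneric("seqLabels"))

#' @rdname barcode-accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname barcode-accessors
setMethod("barcodeSequences", "BarcodeSeqSet", function(x) x@sequences)

#' @rdname barcode-accessors
setMethod("seqLabels", "BarcodeSeqSet", function(x) x@labels)

#' @rdname barcode-accessors
setMethod("labelTable", "BarcodeSeqSet", function(x) x@labelTable)

#' @describeIn BarcodeSeqSet Number of records.
#' @param x A \code{BarcodeSeqSet}.
#' @export
setMethod("length", "BarcodeSeqSet", function(x) length(x@sequences))

#' @describeIn BarcodeSeqSet Record identifiers.
#' @export
setMethod("names", "BarcodeSeqSet", function(x) names(x@sequences))

#' @describeIn BarcodeSeqSet Subset records by index, logical mask or name.
#' @param i Index vector.
#' @param j,drop,... Ignored (matrix-style arguments).
#' @export
setMethod("[", "BarcodeSeqSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x))
  new("BarcodeSeqSet", sequences = x@sequences[i],
      labels = x@labels[if (is.logical(i)) which(i) else i],
      labelTable = x@labelTable)
})

setMethod("show", "BarcodeSeqSet", function(object) {
  C <- nrow(object@labelTable)
  cat(sprintf("BarcodeSeqSet with %d record(s) over %d class(es)\n",
              length(object), C))
  if (length(object)) {
    w <- width(object@sequences)
    cat(sprintf("  sequence length: %d..%d (median %g)\n",
                min(w), max(w), stats::median(w)))
    tab <- table(factor(object@labels, levels = seq_len(C)))
    cat("  records per label: ", paste(tab, collapse = " "), "\n", sep = "")
  }
})

#' Coerce a BarcodeSeqSet to a data.frame
#'
#' @param x A [BarcodeSeqSet-class].
#' @param row.names,optional,... Passed for S3 compatibility, unused.
#' @return \code{data.frame} with columns \code{id}, \code{label},
#'   \code{sequence}.
#' @export
as.data.frame.BarcodeSeqSet <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(id = names(x), label = x@labels,
             sequence = as.character(x@sequences),
             row.names = row.names, stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "BarcodeSeqSet",
          function(x, ...) as.data.frame.BarcodeSeqSet(x, ...))

#' Combine barcode sets
#'
#' @param x,... \code{BarcodeSeqSet} objects sharing a label table.
#' @return The concatenated \code{BarcodeSeqSet}.
#' @export
setMethod("c", "BarcodeSeqSet", function(x, ...) {
  rest <- list(...)
  seqs <- do.call(c, c(list(x@sequences), lapply(rest, slot, "sequences")))
  labs <- c(x@labels, unlist(lapply(rest, slot, "labels")))
  new("BarcodeSeqSet", sequences = seqs, labels = labs,
      labelTable = x@labelTable)
})
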