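#' @useDynLib barcodeCNN, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif predict
#' @importFrom utils read.csv write.table head
NULL

#' Labelled DNA barcode sequence set
#'
#' An S4 container for a set of DNA barcode sequences together with their
#' integer taxonomic-order labels and the label table mapping order names to
#' labels. Sequences are held as a [Biostrings::BStringSet]: raw barcodes
#' may contain IUPAC ambiguity codes and the gap character \code{-} prior to
#' sanitization (the classifier itself operates on the five-letter alphabet
#' \code{A,C,G,T,-}), and the same container carries printable "3-1" encoded
#' token streams, which use the full printable ASCII range.
#'
#' @slot sequences A [Biostrings::BStringSet]; element names are record
#'   identifiers.
#' @slot labels Integer vector, one label per sequence, each in
#'   \code{1..nrow(labelTable)}.
#' @slot labelTable A \code{data.frame} with columns \code{order} (character)
#'   and \code{label} (integer); labels must be exactly \code{1..C}.
#'
#' @seealso [BarcodeSeqSet()] for the constructor, [readBarcodeFasta()],
#'   [readBarcodeCsv()], [splitDataset()].
#' @export
setClass("BarcodeSeqSet",
  representation(
    sequences  = "BStringSet",
    labels     = "integer",
    labelTable = "data.frame"
  )
)

setValidity("BarcodeSeqSet", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@sequences))
    msg <- c(msg, "length(labels) must equal length(sequences)")
  if (length(object@sequences) && any(BiocGenerics::width(object@sequences) < 1L))
    msg <- c(msg, "all sequences must have length >= 1")
  tb <- object@labelTable
  if (nrow(tb)) {
    chk <- tryCatch({ validateLabelTable(tb); NULL }, error = conditionMessage)
    if (!is.null(chk)) msg <- c(msg, chk)
    bad <- !is.na(object@labels) &
      (object@labels < 1L | object@labels > nrow(tb))
    if (any(bad))
      msg <- c(msg, sprintf("labels out of range 1..%d: records %s",
                            nrow(tb), paste(head(which(bad), 5), collapse = ", ")))
  }
  if (any(is.na(object@labels)))
    msg <- c(msg, "labels must not be NA")
  if (length(msg)) msg else TRUE
})

#' Codon ("3-1") encoding dictionary
#'
#' A complete bijection between all \eqn{|A|^k} k-mers over an ordered
#' alphabet and the symbol indices \code{0 .. |A|^k - 1}. With the default
#' alphabet \code{A,C,G,T,-} and \code{k = 3} this is the 125-symbol
#' trinucleotide dictionary used by the "3-1" encoding: each non-overlapping
#' codon of a barcode maps to one symbol. The index of a k-mer is its
#' positional value in base \eqn{|A|} under the alphabet ordering, so the
#' construction is deterministic and needs no stored state beyond the
#' alphabet and k.
#'
#' @slot alphabet Ordered character vector of single characters.
#' @slot k Integer k-mer width (3 for codon encoding, 1 for raw
#'   single-character tokenization).
#' @slot kmers Character vector of all k-mers; \code{kmers[i + 1]} is the
#'   k-mer with index \code{i}.
#' @slot printable Character vector of the printable serializations of each
#'   index (single characters, or two-character escape sequences beyond the
#'   single-character budget), used to write encoded datasets as text.
#'
#' @seealso [buildDictionary()], [encodeSequence()], [toPrintable()].
#' @export
setClass("CodonDictionary",
  representation(
    alphabet  = "character",
    k         = "integer",
    kmers     = "character",
    printable = "character"
  )
)

setValidity("CodonDictionary", function(object) {
  msg <- character()
  if (any(nchar(object@alphabet) != 1L) || anyDuplicated(object@alphabet))
    msg <- c(msg, "alphabet must be unique single characters")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  D <- length(object@alphabet)^object@k
  if (length(object@kmers) != D)
    msg <- c(msg, sprintf("kmers must enumerate all %d k-mers", D))
  if (anyDuplicated(object@kmers))
    msg <- c(msg, "kmers must be distinct (bijection)")
  if (length(object@printable) != D || anyDuplicated(object@printable))
    msg <- c(msg, "printable table must hold one distinct code per index")
  if (length(msg)) msg else TRUE
})

#' Encoded (tokenized) sequence
#'
#' The token stream produced by encoding a sanitized sequence through a
#' [CodonDictionary]: 0-based symbol indices, one per non-overlapping k-mer
#' after right-padding with \code{-} to a multiple of k. The original
#' (pre-padding) character length is retained so decoding can trim the pad.
#'
#' @slot tokens Integer vector of symbol indices in \code{0 .. D-1}.
#' @slot sourceLength Integer, character length of the source sequence.
#' @seealso [encodeSequence()], [decodeSequence()], [quantizeFrame()].
#' @export
setClass("EncodedSequence",
  representation(tokens = "integer", sourceLength = "integer")
)

setValidity("EncodedSequence", function(object) {
  if (length(object@sourceLength) != 1L || is.na(object@sourceLength) ||
      object@sourceLength < 0L)
    return("sourceLength must be a single non-negative integer")
  if (any(is.na(object@tokens)) || any(object@tokens < 0L))
    return("tokens must be non-negative integers")
  TRUE
})

#' Character-level temporal CNN classifier
#'
#' Holds the architecture description (see [modelConfig()]), the parameter
#' arrays of every convolutional and fully-connected layer, and the seed the
#' parameters were initialized from. Parameters of convolution layer l form a
#' matrix of shape \code{features_l x (inChannels_l * kernel_l)} so the layer
#' is evaluated as a single matrix product against an im2col expansion of its
#' input.
#'
#' @slot config Named list, the validated model configuration.
#' @slot params Named list with elements \code{conv} (list of
#'   \code{list(W, b)}), \code{fc} (list of \code{list(W, b)}) and \code{out}
#'   (\code{list(W, b)}).
#' @slot seed Integer seed used for initialization.
#' @slot version Checkpoint format version string.
#' @seealso [buildModel()], [trainClassifier()], [predict()].
#' @export
setClass("CNNClassifier",
  representation(
    config  = "list",
    params  = "list",
    seed    = "integer",
    version = "character"
  )
)
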