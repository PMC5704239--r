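#' Default barcode alphabet
#'
#' The five-character alphabet of aligned DNA barcode data: the four bases
#' plus the gap character \code{-}, which the classifier treats as an
#' ordinary fifth character rather than as an alignment gap to be resolved.
#' The ordering \code{A < C < G < T < -} fixes the positional indexing of
#' every dictionary built from it.
#'
#' @return Character vector \code{c("A","C","G","T","-")}.
#' @export
barcodeAlphabet <- function() c("A", "C", "G", "T", "-")

## printable single-character codes: ASCII 33..126 minus '!' (escape prefix),
## '"' (CSV quoting) and ',' (CSV separator) -> 91 symbols; index i is
## serialized as floor(i/91) copies of '!' followed by singles[i %% 91 + 1].
.printableSingles <- function() {
  setdiff(intToUtf8(33:126, multiple = TRUE), c("!", "\"", ","))
}

.printableTable <- function(D) {
  singles <- .printableSingles()
  i <- seq_len(D) - 1L
  paste0(strrep("!", i %/% length(singles)),
         singles[i %% length(singles) + 1L])
}

#' Build a k-mer encoding dictionary
#'
#' Enumerates all \eqn{|A|^k} k-mers over the alphabet and assigns each the
#' index equal to its positional value in base \eqn{|A|} under the alphabet
#' ordering (first character most significant). The construction is a
#' complete bijection, so encoding is injective and decodable. \code{k = 3}
#' over the default alphabet yields the 125-symbol codon ("3-1") dictionary;
#' \code{k = 1} is the identity tokenization used for raw
#' single-character frames.
#'
#' @param alphabet Ordered character vector (default [barcodeAlphabet()]).
#' @param k k-mer width, a positive integer.
#' @return A [CodonDictionary-class].
#' @examples
#' d <- buildDictionary()
#' dictionarySize(d)        # 125
#' kmerIndex(d, "ACG")      # 7 = 0*25 + 1*5 + 2
#' @export
buildDictionary <- function(alphabet = barcodeAlphabet(), k = 3L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (!length(alphabet)) stop("alphabet must be non-empty")
  A <- length(alphabet)
  ## index = sum pos(s_i) * A^(k-1-i): last position varies fastest
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, alphabet, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, rev(grid))
  new("CodonDictionary", alphabet = alphabet, k = k, kmers = kmers,
      printable = .printableTable(A^k))
}

#' Dictionary accessors
#'
#' \code{dictionarySize} returns the number of symbols \eqn{D = |A|^k};
#' \code{kmerIndex} maps k-mers to their 0-based symbol indices;
#' \code{kmerAt} is the inverse.
#'
#' @param dict A [CodonDictionary-class].
#' @param kmer Character vector of k-mers.
#' @param index Integer vector of symbol indices in \code{0..D-1}.
#' @return See descriptions.
#' @export
dictionarySize <- function(dict) length(dict@kmers)

#' @rdname dictionarySize
#' @export
kmerIndex <- function(dict, kmer) {
  i <- match(kmer, dict@kmers)
  if (anyNA(i)) stop("k-mer(s) not in dictionary: ",
                     paste(kmer[is.na(i)], collapse = ", "))
  i - 1L
}

#' @rdname dictionarySize
#' @export
kmerAt <- function(dict, index) {
  if (any(index < 0L | index >= dictionarySize(dict)))
    stop("symbol index out of range 0..", dictionarySize(dict) - 1L)
  dict@kmers[index + 1L]
}

setMethod("length", "CodonDictionary", function(x) length(x@kmers))

setMethod("show", "CodonDictionary", function(object) {
  cat(sprintf("CodonDictionary: %d-mers over {%s}, %d symbols\n",
              object@k, paste(object@alphabet, collapse = ","),
              length(object@kmers)))
})

setMethod("show", "EncodedSequence", function(object) {
  cat(sprintf("EncodedSequence: %d token(s) from %d character(s)\n",
              length(object@tokens), object@sourceLength))
})

setMethod("length", "EncodedSequence", function(x) length(x@tokens))

#' Token stream accessors
#'
#' \code{tokens} returns the 0-based token indices of an encoded sequence;
#' \code{sourceLength} its original character length before padding.
#'
#' @param x An [EncodedSequence-class].
#' @return Integer vector / integer scalar.
#' @export
tokens <- function(x) x@tokens

#' @rdname tokens
#' @export
sourceLength <- function(x) x@sourceLength

#' Sanitize a sequence to the model alphabet
#'
#' Uppercases the sequence and replaces every character outside the alphabet
#' (IUPAC ambiguity codes, stray symbols) by \code{-}. Length is preserved so
#' the codon reading frame of the surrounding sequence is unchanged; this is
#' a total function with no error cases.
#'
#' @param sequence Character vector of sequences.
#' @param alphabet Target alphabet (default [barcodeAlphabet()]).
#' @return Character vector of sanitized sequences.
#' @examples
#' sanitizeSequence("acgtN")  # "ACGT-"
#' @export
sanitizeSequence <- function(sequence, alphabet = barcodeAlphabet()) {
  cls <- paste0("[^", paste(gsub("([][^\\\\-])", "\\\\\\1", alphabet),
                            collapse = ""), "]")
  gsub(cls, "-", toupper(sequence))
}

.padChar <- function(dict) {
  if ("-" %in% dict@alphabet) "-" else dict@alphabet[length(dict@alphabet)]
}

#' Encode a sanitized sequence into dictionary tokens
#'
#' Right-pads the sequence with \code{-} to a multiple of k, splits it into
#' non-overlapping k-mers left to right, and maps each through the
#' dictionary. The original length is recorded so [decodeSequence()] can trim
#' the padding; \code{decodeSequence(encodeSequence(s)) == s} for any
#' sanitized \code{s}.
#'
#' @param sequence A single sanitized sequence string.
#' @param dict A [CodonDictionary-class].
#' @return An [EncodedSequence-class].
#' @examples
#' d <- buildDictionary()
#' tokens(encodeSequence("ACGTAC", d))  # 7, 76
#' @export
encodeSequence <- function(sequence, dict = buildDictionary()) {
  stopifnot(isSingleString(sequence) || (is.character(sequence) &&
                                           length(sequence) == 1L))
  n <- nchar(sequence)
  if (n == 0L)
    return(new("EncodedSequence", tokens = integer(), sourceLength = 0L))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- match(chars, dict@alphabet)
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1]
    stop(sprintf("unsanitized character '%s' at position %d; run sanitizeSequence() first",
                 chars[i], i))
  }
  k <- dict@k
  pad <- (k - n %% k) %% k
  if (pad > 0L)
    pos <- c(pos, rep(match(.padChar(dict), dict@alphabet), pad))
  A <- length(dict@alphabet)
  m <- matrix(pos - 1L, nrow = k)
  toks <- as.integer(colSums(m * A^((k - 1):0)))
  new("EncodedSequence", tokens = toks, sourceLength = as.integer(n))
}

#' Decode dictionary tokens back to a sequence
#'
#' Inverse of [encodeSequence()]: concatenates the k-mers of the token
#' stream and trims to the recorded source length.
#'
#' @param encoded An [EncodedSequence-class] (or integer token vector, in
#'   which case no trimming occurs).
#' @param dict The dictionary used for encoding.
#' @return Sequence string.
#' @export
decodeSequence <- function(encoded, dict = buildDictionary()) {
  toks <- if (is(encoded, "EncodedSequence")) encoded@tokens
          else as.integer(encoded)
  if (any(toks < 0L | toks >= dictionarySize(dict)))
    stop("token out of range 0..", dictionarySize(dict) - 1L)
  s <- paste(dict@kmers[toks + 1L], collapse = "")
  if (is(encoded, "EncodedSequence")) substr(s, 1L, encoded@sourceLength)
  else s
}

#' Printable serialization of encoded sequences
#'
#' Writes a token stream as printable text so encoded datasets can be stored
#' in the same two-column CSV dialect as raw sequences. Index \code{i} is
#' serialized as \code{floor(i/91)} copies of the escape character \code{!}
#' followed by one of 91 printable ASCII symbols (ASCII 33-126 minus
#' \code{!}, \code{"} and \code{,}); the default 125-symbol dictionary uses
#' single characters for indices 0-90 and two-character escapes above.
#'
#' @param encoded An [EncodedSequence-class].
#' @param dict The dictionary.
#' @return \code{toPrintable}: a string; \code{fromPrintable}: an
#'   [EncodedSequence-class] (source length inferred as
#'   \code{k * n_tokens}).
#' @examples
#' d <- buildDictionary()
#' toPrintable(encodeSequence("ACGTAC", d), d)
#' @export
toPrintable <- function(encoded, dict = buildDictionary()) {
  toks <- if (is(encoded, "EncodedSequence")) encoded@tokens
          else as.integer(encoded)
  if (any(toks < 0L | toks >= dictionarySize(dict)))
    stop("token out of range 0..", dictionarySize(dict) - 1L)
  paste(dict@printable[toks + 1L], collapse = "")
}

#' @rdname toPrintable
#' @param text Printable serialization to parse.
#' @export
fromPrintable <- function(text, dict = buildDictionary()) {
  stopifnot(is.character(text), length(text) == 1L)
  singles <- .printableSingles()
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- integer(0); esc <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "!") { esc <- esc + 1L; next }
    j <- match(ch, singles)
    if (is.na(j))
      stop(sprintf("character '%s' at position %d is not in the printable table",
                   ch, i))
    idx <- esc * length(singles) + j - 1L
    if (idx >= dictionarySize(dict))
      stop(sprintf("printable code at position %d maps to index %d, beyond the %d-symbol dictionary",
                   i, idx, dictionarySize(dict)))
    toks <- c(toks, idx); esc <- 0L
  }
  if (esc > 0L) stop("dangling escape character(s) at end of input")
  new("EncodedSequence", tokens = toks,
      sourceLength = as.integer(dict@k * length(toks)))
}

#' One-hot quantization of a token stream
#'
#' Builds the binary \eqn{D \times L} frame fed to the network: column j
#' carries a single 1 in the row of the j-th token; streams shorter than the
#' frame are padded with all-zero columns, longer ones are truncated at L.
#' With \code{order = "reverse"} the kept tokens fill the frame in reverse
#' (column 1 holds the last kept token), mirroring the backward quantization
#' of early character-level text CNNs.
#'
#' @param encoded An [EncodedSequence-class] or integer token vector.
#' @param dict Dictionary (supplies the number of rows D); alternatively
#'   pass \code{D} directly.
#' @param frameLength Frame length L (columns).
#' @param order \code{"forward"} (default) or \code{"reverse"}.
#' @param D Number of symbol rows; defaults to \code{dictionarySize(dict)}.
#' @return Integer matrix of shape \code{D x frameLength}.
#' @examples
#' f <- quantizeFrame(encodeSequence("ACGTAC"), frameLength = 4)
#' which(f[, 1] == 1)  # row 8 = token 7
#' @export
quantizeFrame <- function(encoded, dict = buildDictionary(),
                          frameLength = 258L,
                          order = c("forward", "reverse"),
                          D = dictionarySize(dict)) {
  order <- match.arg(order)
  L <- as.integer(frameLength)
  if (L < 1L) stop("frameLength must be >= 1")
  toks <- if (is(encoded, "EncodedSequence")) encoded@tokens
          else as.integer(encoded)
  if (any(toks < 0L | toks >= D)) stop("token out of range 0..", D - 1L)
  kept <- toks[seq_len(min(length(toks), L))]
  if (order == "reverse") kept <- rev(kept)
  m <- matrix(0L, nrow = D, ncol = L)
  if (length(kept)) m[cbind(kept + 1L, seq_along(kept))] <- 1L
  m
}

#' Token matrix for a batch of sequences
#'
#' Sanitizes, encodes and frames every sequence of a set into an integer
#' matrix of shape \code{frameLength x n} holding 0-based token indices,
#' with \code{-1} marking blank (all-zero) frame columns. This is the
#' compact input the C++ training routines expand to one-hot on the fly.
#'
#' @param x A [BarcodeSeqSet-class] or character vector of sequences.
#' @param dict Dictionary defining the tokenization.
#' @param frameLength Frame length L.
#' @param order Quantization order, as in [quantizeFrame()].
#' @return Integer matrix \code{L x n}.
#' @export
tokenMatrix <- function(x, dict = buildDictionary(), frameLength = 258L,
                        order = c("forward", "reverse")) {
  order <- match.arg(order)
  seqs <- if (is(x, "BarcodeSeqSet")) as.character(barcodeSequences(x))
          else as.character(x)
  L <- as.integer(frameLength)
  out <- matrix(-1L, nrow = L, ncol = length(seqs))
  seqs <- sanitizeSequence(seqs, dict@alphabet)
  for (i in seq_along(seqs)) {
    toks <- encodeSequence(seqs[i], dict)@tokens
    kept <- toks[seq_len(min(length(toks), L))]
    if (order == "reverse") kept <- rev(kept)
    if (length(kept)) out[seq_along(kept), i] <- kept
  }
  out
}

#' Export / import a dictionary as CSV
#'
#' Two-column CSV (\code{kmer,index}) for audit of the exact encoding used
#' by a run. Import verifies that the file describes a canonical
#' positional-index dictionary and rebuilds it.
#'
#' @param dict A [CodonDictionary-class].
#' @param path CSV path.
#' @return \code{readDictionary}: the reconstructed dictionary.
#' @export
writeDictionary <- function(dict, path) {
  write.table(data.frame(kmer = dict@kmers,
                         index = seq_along(dict@kmers) - 1L),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDictionary
#' @export
readDictionary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "integer"))
  df <- df[order(df$index), ]
  k <- nchar(df$kmer[1])
  A <- round(nrow(df)^(1 / k))
  if (A^k != nrow(df))
    stop("dictionary file is not complete: ", nrow(df),
         " entries cannot be |A|^", k)
  alphabet <- substr(df$kmer[seq_len(A)], k, k)
  dict <- buildDictionary(alphabet, k)
  if (!identical(dict@kmers, df$kmer))
    stop("dictionary file does not follow the canonical positional indexing")
  dict
}
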