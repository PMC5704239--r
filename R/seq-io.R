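#' Validate a label table
#'
#' A label table maps taxonomic order names to the integer class labels the
#' classifier predicts. Labels must be exactly \code{1..C} with no gaps or
#' duplicates and order names must be unique.
#'
#' @param tb \code{data.frame} with columns \code{order} and \code{label}.
#' @return The table, invisibly, with \code{label} coerced to integer.
#' @export
validateLabelTable <- function(tb) {
  if (!is.data.frame(tb) || !all(c("order", "label") %in% names(tb)))
    stop("label table must be a data.frame with columns 'order' and 'label'")
  lab <- suppressWarnings(as.integer(tb$label))
  if (any(is.na(lab)))
    stop("label table: non-integer label value")
  if (!identical(sort(lab), seq_len(nrow(tb))))
    stop("label table: labels must be exactly 1..", nrow(tb),
         " with no gaps or duplicates")
  if (anyDuplicated(tb$order))
    stop("label table: duplicated order name(s): ",
         paste(unique(tb$order[duplicated(tb$order)]), collapse = ", "))
  tb$label <- lab
  invisible(tb)
}

#' Label table of the nine BOLD orders
#'
#' The mapping from taxonomic order names to integer labels 1..9 used for
#' the nine-order barcode classification benchmark (orders downloaded from
#' the Barcode of Life Data Systems public portal).
#'
#' @return A validated label table \code{data.frame}.
#' @examples
#' boldOrderLabels()
#' @export
boldOrderLabels <- function() {
  validateLabelTable(data.frame(
    order = c("Chaetothyriomycetes", "Diptera", "Echinoida", "Forcipulatida",
              "Lepidoptera", "Onygenales", "Pezizomycetes", "Scleractinia",
              "Valvatida"),
    label = 1:9
  ))
}

#' Read / write a label table as two-column CSV
#'
#' Plain CSV with a header row, columns \code{order,label}.
#'
#' @param path File path.
#' @return \code{readLabelTable}: a validated label table.
#' @export
readLabelTable <- function(path) {
  if (!file.exists(path)) stop("label table file not found: ", path)
  validateLabelTable(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readLabelTable
#' @param tb A label table.
#' @export
writeLabelTable <- function(tb, path) {
  tb <- validateLabelTable(tb)
  write.table(tb, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## default header rule: order name is the last '|'-separated token
.headerOrder <- function(headers, labelSource) {
  if (is.function(labelSource))
    return(vapply(headers, labelSource, FUN.VALUE = "", USE.NAMES = FALSE))
  sep   <- if (!is.null(labelSource$sep)) labelSource$sep else "|"
  index <- if (!is.null(labelSource$index)) labelSource$index else -1L
  vapply(strsplit(headers, sep, fixed = TRUE), function(tok) {
    i <- if (index < 0L) length(tok) + 1L + index else index
    if (i < 1L || i > length(tok)) NA_character_ else trimws(tok[i])
  }, FUN.VALUE = "")
}

#' Read labelled barcodes from a FASTA file
#'
#' Reads a multi-line FASTA file (BOLD-style "fas" export) into a
#' [BarcodeSeqSet-class]. Sequences are uppercased and line breaks removed;
#' the class label of each record is derived from its header through a
#' configurable rule, since header layouts vary between data sources and are
#' never guessed.
#'
#' @param path FASTA file path.
#' @param labelTable Label table mapping order names to labels.
#' @param labelSource Either a function \code{header -> order name}, or a
#'   list with \code{sep} (split character, default \code{"|"}) and
#'   \code{index} (token position; negative counts from the end, default
#'   \code{-1}, i.e. the last token).
#' @return A [BarcodeSeqSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x|Valvatida", "ACGT"), fa)
#' readBarcodeFasta(fa, boldOrderLabels())
#' @export
readBarcodeFasta <- function(path, labelTable,
                             labelSource = list(sep = "|", index = -1L)) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  labelTable <- validateLabelTable(labelTable)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(BarcodeSeqSet(character(), integer(), labelTable))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: sequence data before first header at line ",
         nonblank[1])
  seqs <- readDNAStringSet(path, format = "fasta")
  headers <- names(seqs)
  orders <- .headerOrder(headers, labelSource)
  lab <- labelTable$label[match(orders, labelTable$order)]
  if (any(is.na(lab))) {
    bad <- which(is.na(lab))[1]
    stop(sprintf(
      "record '%s': order name '%s' absent from the label table",
      headers[bad], orders[bad]))
  }
  BarcodeSeqSet(toupper(as.character(seqs)), lab, labelTable, ids = headers)
}

#' Read / write labelled barcodes as two-column CSV
#'
#' The CSV dialect is headerless: column 1 is the integer class label,
#' column 2 the double-quoted sequence string (raw bases or a printable
#' encoded stream). On read, record ids are synthesized as row numbers.
#'
#' @param path CSV file path.
#' @param labelTable Optional label table; defaults to an anonymous table
#'   spanning the labels present.
#' @return \code{readBarcodeCsv}: a [BarcodeSeqSet-class].
#' @export
readBarcodeCsv <- function(path, labelTable = NULL) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  if (file.size(path) == 0L || !length(readLines(path, n = 1L, warn = FALSE)))
    return(BarcodeSeqSet(character(), integer(), labelTable))
  df <- read.csv(path, header = FALSE, colClasses = "character",
                 stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("CSV must have two columns (label, sequence)")
  lab <- suppressWarnings(as.integer(df[[1]]))
  bad <- which(is.na(lab) | as.character(lab) != trimws(df[[1]]))
  if (length(bad))
    stop("non-integer label field at row ", bad[1], ": '", df[[1]][bad[1]], "'")
  if (any(!nzchar(df[[2]])))
    stop("empty sequence field at row ", which(!nzchar(df[[2]]))[1])
  BarcodeSeqSet(df[[2]], lab, labelTable, ids = as.character(seq_len(nrow(df))))
}

#' @rdname readBarcodeCsv
#' @param x A [BarcodeSeqSet-class] (or data.frame with \code{label},
#'   \code{sequence} columns).
#' @export
writeBarcodeCsv <- function(x, path) {
  df <- if (is.data.frame(x)) x else as.data.frame(x)
  if (any(grepl('"', df$sequence, fixed = TRUE)))
    stop("sequences must not contain embedded double quotes")
  out <- data.frame(label = as.integer(df$label), sequence = df$sequence)
  write.table(out, path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = 2L)
  invisible(path)
}

#' Specify a train / cross-validation / test split
#'
#' Either fractions summing to 1 or explicit subset counts summing to the
#' dataset size. Fractional sizes are resolved as \code{floor(N * fraction)}
#' per subset with the remainder assigned to the training subset, so the
#' partition is deterministic and order-independent.
#'
#' @param train,cv,test Fractions in \code{[0, 1]} summing to 1 (default the
#'   benchmark proportions 78.72\% / 11.45\% / 9.83\%).
#' @param counts Optional integer vector \code{c(train, cv, test)} of exact
#'   subset sizes, overriding the fractions.
#' @param seed Integer seed determining the random permutation.
#' @param stratify Logical; if \code{TRUE} the split is applied per class.
#'   The default is a plain uniform random split of the whole set.
#' @return A validated list of class \code{"splitSpec"}.
#' @export
splitSpec <- function(train = 0.7872, cv = 0.1145, test = 0.0983,
                      counts = NULL, seed = 1L, stratify = FALSE) {
  if (is.null(counts)) {
    fr <- c(train, cv, test)
    if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-9)
      stop("split fractions must lie in [0,1] and sum to 1")
  } else {
    counts <- as.integer(counts)
    if (length(counts) != 3L || any(counts < 0L))
      stop("counts must be three non-negative integers (train, cv, test)")
  }
  structure(list(train = train, cv = cv, test = test, counts = counts,
                 seed = as.integer(seed), stratify = isTRUE(stratify)),
            class = "splitSpec")
}

## run expr with a private RNG stream seeded by `seed`,
## restoring the caller's RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.splitSizes <- function(N, spec) {
  if (!is.null(spec$counts)) {
    if (sum(spec$counts) != N)
      stop("explicit counts sum to ", sum(spec$counts),
           " but the dataset has ", N, " records")
    return(spec$counts)
  }
  n_cv <- floor(N * spec$cv); n_te <- floor(N * spec$test)
  n_tr <- floor(N * spec$train)
  c(n_tr + (N - n_tr - n_cv - n_te), n_cv, n_te)
}

#' Split a dataset into train / cross-validation / test subsets
#'
#' Records are randomly partitioned according to a [splitSpec()]: the
#' permutation is fully determined by the spec's seed, the three subsets are
#' disjoint and their union is the input. With \code{stratify = TRUE} the
#' same rule is applied within each class.
#'
#' @param x A [BarcodeSeqSet-class] (or anything with \code{length} and
#'   \code{[} when \code{stratify = FALSE}).
#' @param spec A [splitSpec()].
#' @return Named list with elements \code{train}, \code{cv}, \code{test}.
#' @examples
#' bs <- BarcodeSeqSet(rep("ACGT", 10), rep(1:2, 5))
#' sapply(splitDataset(bs, splitSpec(0.7, 0.2, 0.1, seed = 42)), length)
#' @export
splitDataset <- function(x, spec = splitSpec()) {
  N <- length(x)
  if (N == 0L) stop("cannot split an empty dataset")
  grp <- function(p, sz) split(p, factor(rep.int(1:3, sz), levels = 1:3))
  idx <- if (spec$stratify && is(x, "BarcodeSeqSet")) {
    if (!is.null(spec$counts))
      stop("stratified splitting requires fractions, not explicit counts")
    parts <- withSeed(spec$seed, lapply(split(seq_len(N), seqLabels(x)),
      function(ii) grp(ii[sample.int(length(ii))],
                       .splitSizes(length(ii), spec))))
    lapply(as.character(1:3), function(g)
      unlist(lapply(parts, `[[`, g), use.names = FALSE))
  } else {
    sz <- .splitSizes(N, spec)
    grp(withSeed(spec$seed, sample.int(N)), sz)
  }
  list(train = x[idx[[1]]], cv = x[idx[[2]]], test = x[idx[[3]]])
}

#' Summarize split sizes as percentages
#'
#' Percentages are rounded half-to-even to two decimals; counts are the
#' authoritative description of a split, percentages are presentation.
#'
#' @param sizes Integer vector of subset sizes (train, cv, test).
#' @return \code{data.frame} with subset, count and percentage columns.
#' @export
splitSummary <- function(sizes) {
  N <- sum(sizes)
  data.frame(subset = c("train", "cv", "test"),
             count = as.integer(sizes),
             percent = round(100 * sizes / N, 2))
}

.CACHE_MAGIC <- "barcodeCNN-tensor-cache-v1"

#' Cache prepared tensors on disk
#'
#' A small versioned container for preprocessed training inputs (token
#' matrices, label vectors) so repeated runs skip re-encoding. The payload is
#' serialized together with a magic string; readers refuse files whose magic
#' does not match the current format version.
#'
#' @param object Any serializable R object.
#' @param path Destination file.
#' @return \code{writeTensorCache}: \code{path} invisibly;
#'   \code{readTensorCache}: the cached object.
#' @export
writeTensorCache <- function(object, path) {
  saveRDS(list(magic = .CACHE_MAGIC, payload = object), path)
  invisible(path)
}

#' @rdname writeTensorCache
#' @export
readTensorCache <- function(path) {
  x <- readRDS(path)
  if (!identical(x$magic, .CACHE_MAGIC))
    stop("not a barcodeCNN tensor cache (bad magic): ", path)
  x$payload
}
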