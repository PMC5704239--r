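# Independent brute-force oracles and small fixture builders.

# literal double-loop evaluation of the temporal convolution sum
bruteConv <- function(g, f, d) {
  n <- length(g); k <- length(f); cc <- k - d + 1
  m <- (n - k) %/% d + 1
  h <- numeric(m)
  for (y in seq_len(m)) {
    acc <- 0
    for (x in seq_len(k)) acc <- acc + f[x] * g[y * d - x + cc]
    h[y] <- acc
  }
  h
}

# literal double-loop evaluation of the temporal max-pool
brutePool <- function(g, k, d) {
  n <- length(g); cc <- k - d + 1
  m <- (n - k) %/% d + 1
  h <- numeric(m)
  for (y in seq_len(m)) {
    best <- -Inf
    for (x in seq_len(k)) best <- max(best, g[y * d - x + cc])
    h[y] <- best
  }
  h
}

# base-|A| positional value of a k-mer, computed independently of the package
bruteKmerIndex <- function(kmer, alphabet) {
  chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
  pos <- match(chars, alphabet) - 1L
  as.integer(sum(pos * length(alphabet)^(rev(seq_along(pos)) - 1L)))
}

# per-cell counting implementation of accuracy / recall / precision
bruteMetrics <- function(cm) {
  C <- nrow(cm); total <- sum(cm)
  rec <- numeric(C); prec <- numeric(C)
  for (i in seq_len(C)) {
    rt <- sum(cm[i, ]); ct <- sum(cm[, i])
    rec[i] <- if (rt > 0) cm[i, i] / rt else 0
    prec[i] <- if (ct > 0) cm[i, i] / ct else 0
  }
  list(accuracy = sum(diag(cm)) / total,
       macroRecall = mean(rec), macroPrecision = mean(prec),
       recall = rec, precision = prec)
}

randomCleanSeq <- function(n, gaps = TRUE) {
  ab <- if (gaps) c("A", "C", "G", "T", "-") else c("A", "C", "G", "T")
  paste(sample(ab, n, replace = TRUE), collapse = "")
}

writeTempFasta <- function(records, widths = 60) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1, nchar(s), by = widths)
    writeLines(substring(s, starts, pmin(starts + widths - 1, nchar(s))), con)
  }
  close(con)
  path
}

# tiny two-class set separable by a class-unique codon token: the marker
# codons contain a gap, so they can never arise from the gap-free background
separableToySet <- function(perClass = 24, seed = 42) {
  withr::with_seed(seed, {
    mk <- function(marker) vapply(seq_len(perClass), function(i)
      paste0(randomCleanSeq(12, gaps = FALSE), marker,
             randomCleanSeq(12, gaps = FALSE)), "")
    BarcodeSeqSet(c(mk("A-A"), mk("G-G")), rep(1:2, each = perClass))
  })
}

smallModel <- function(C = 2, L = 20, D = 125, seed = 1) {
  modelConfig(frameLength = L, dictSize = D, nClasses = C,
              convFeatures = 16L, convKernels = 3L, convStrides = 1L,
              poolWidths = NA_integer_, fcWidths = 16L, dropout = 0,
              seed = seed)
}
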