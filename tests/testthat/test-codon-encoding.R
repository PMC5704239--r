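test_that("the default codon dictionary has 125 bijective entries", {
  d <- buildDictionary()
  expect_identical(dictionarySize(d), 125L)
  expect_identical(anyDuplicated(d@kmers), 0L)
  expect_identical(kmerIndex(d, "AAA"), 0L)
  expect_identical(kmerIndex(d, "ACG"), 7L)
  expect_identical(kmerIndex(d, "---"), 124L)
  expect_identical(kmerAt(d, kmerIndex(d, d@kmers)), d@kmers)
})

test_that("small and degenerate dictionaries enumerate exhaustively", {
  d2 <- buildDictionary(c("A", "C"), 2L)
  expect_identical(d2@kmers, c("AA", "AC", "CA", "CC"))
  expect_identical(kmerIndex(d2, c("AA", "AC", "CA", "CC")), 0:3)

  d1 <- buildDictionary(k = 1L)
  expect_identical(d1@kmers, c("A", "C", "G", "T", "-"))
  expect_identical(tokens(encodeSequence("GATC", d1)), c(2L, 0L, 3L, 1L))
})

test_that("dictionary completeness and positional indexing hold for many alphabets", {
  pool <- c("A", "C", "G", "T", "-", "R", "Y", "N")
  for (A in c(2, 3, 5, 8)) {
    for (k in 1:3) {
      if (A^k > 5000) next
      ab <- pool[seq_len(A)]
      d <- buildDictionary(ab, k)
      expect_identical(length(d@kmers), as.integer(A^k))
      expect_identical(anyDuplicated(d@kmers), 0L)
      picks <- sample(d@kmers, min(20, length(d@kmers)))
      expect_identical(kmerIndex(d, picks),
                       vapply(picks, bruteKmerIndex, 0L, alphabet = ab,
                              USE.NAMES = FALSE))
    }
  }
})

test_that("sanitize uppercases, maps foreign characters to gaps, keeps length", {
  expect_identical(sanitizeSequence("acgtN"), "ACGT-")
  expect_identical(sanitizeSequence("ACGT"), "ACGT")
  expect_identical(sanitizeSequence(""), "")
  set.seed(2)
  iupac <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N", "-", ".")
  s <- paste(sample(iupac, 1000, replace = TRUE), collapse = "")
  out <- sanitizeSequence(s)
  expect_identical(nchar(out), 1000L)
  expect_true(all(strsplit(out, "")[[1]] %in% barcodeAlphabet()))
})

test_that("encoding pads to full codons and maps by positional value", {
  d <- buildDictionary()
  expect_identical(tokens(encodeSequence("ACGTAC", d)), c(7L, 76L))
  e <- encodeSequence("ACGTA", d)
  expect_identical(tokens(e), c(7L, 79L))   # TA- = 3*25 + 0*5 + 4
  expect_identical(sourceLength(e), 5L)
  expect_identical(decodeSequence(e, d), "ACGTA")
  e0 <- encodeSequence("", d)
  expect_identical(tokens(e0), integer())
  expect_identical(decodeSequence(e0, d), "")
  expect_error(encodeSequence("ACGN", d), "position 4")
  expect_error(decodeSequence(c(0L, 125L), d), "range")
})

test_that("encode/decode is the identity on random sanitized sequences", {
  d <- buildDictionary()
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:700, 1)
    s <- randomCleanSeq(n)
    e <- encodeSequence(s, d)
    expect_identical(length(tokens(e)), as.integer(ceiling(n / 3)))
    expect_true(all(tokens(e) >= 0L & tokens(e) < 125L))
    expect_identical(decodeSequence(e, d), s)
  }
})

test_that("encoding is injective on equal-length sequences", {
  d <- buildDictionary()
  set.seed(12)
  seqs <- unique(vapply(1:200, function(i) randomCleanSeq(30), ""))
  enc <- vapply(seqs, function(s)
    paste(tokens(encodeSequence(s, d)), collapse = ","), "")
  expect_identical(anyDuplicated(enc), 0L)
})

test_that("printable serialization is reversible and rejects foreign text", {
  d <- buildDictionary()
  expect_identical(toPrintable(0L, d), d@printable[1])
  expect_identical(nchar(d@printable[1]), 1L)    # single char for index 0
  expect_identical(nchar(d@printable[125]), 2L)  # escaped beyond 91 singles
  expect_false(any(grepl('[",]', d@printable)))  # CSV-safe codes
  set.seed(8)
  for (i in 1:50) {
    toks <- sample(0:124, sample(1:80, 1), replace = TRUE)
    txt <- toPrintable(toks, d)
    expect_identical(tokens(fromPrintable(txt, d)), as.integer(toks))
  }
  expect_error(fromPrintable("é", d), "printable table")
  expect_error(fromPrintable("ab!", d), "dangling")
  d1 <- buildDictionary(k = 1L)
  expect_error(fromPrintable("zz", d1), "beyond")
})

test_that("one-hot frames place single ones and obey truncation/padding", {
  f <- quantizeFrame(c(7L, 76L), frameLength = 4, D = 125)
  expect_identical(dim(f), c(125L, 4L))
  expect_identical(sum(f), 2L)
  expect_identical(f[8, 1], 1L)
  expect_identical(f[77, 2], 1L)
  expect_identical(colSums(f), c(1, 1, 0, 0))

  long <- quantizeFrame(rep(3L, 10), frameLength = 4, D = 5)
  expect_identical(sum(colSums(long) > 0), 4L)

  rev <- quantizeFrame(c(1L, 2L, 3L), frameLength = 5, D = 5,
                       order = "reverse")
  expect_identical(which(rev[, 1] == 1L), 4L)  # last token first
  expect_identical(which(rev[, 3] == 1L), 2L)

  set.seed(4)
  for (i in 1:25) {
    toks <- sample(0:124, sample(0:40, 1), replace = TRUE)
    L <- sample(1:30, 1)
    q <- quantizeFrame(toks, frameLength = L, D = 125)
    expect_true(all(colSums(q) %in% c(0L, 1L)))
    expect_identical(sum(q), min(length(toks), L))
  }
})

test_that("token matrices agree with per-sequence quantization", {
  d <- buildDictionary()
  set.seed(9)
  seqs <- vapply(c(10, 40, 90), randomCleanSeq, "")
  tm <- tokenMatrix(seqs, d, frameLength = 20)
  expect_identical(dim(tm), c(20L, 3L))
  for (i in 1:3) {
    toks <- tokens(encodeSequence(seqs[i], d))
    kept <- toks[seq_len(min(length(toks), 20))]
    expect_identical(tm[seq_along(kept), i], kept)
    if (length(kept) < 20)
      expect_true(all(tm[(length(kept) + 1):20, i] == -1L))
  }
})

test_that("dictionaries export to CSV and re-import canonically", {
  d <- buildDictionary()
  path <- tempfile(fileext = ".csv")
  writeDictionary(d, path)
  expect_identical(length(readLines(path)), 126L)  # header + 125 entries
  d2 <- readDictionary(path)
  expect_identical(d2@kmers, d@kmers)
  expect_identical(d2@alphabet, d@alphabet)

  df <- utils::read.csv(path)
  df$kmer[c(1, 2)] <- df$kmer[c(2, 1)]   # break canonical order
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(readDictionary(path), "canonical")
})

test_that("invalid dictionary requests are rejected", {
  expect_error(buildDictionary(k = 0L), "positive")
  expect_error(buildDictionary(character(), 2L), "non-empty")
})
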