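test_that("temporal convolution reproduces worked examples", {
  expect_equal(temporalConvolution(c(1, 2, 3, 4), c(1, 1)), c(3, 5, 7))
  g <- rnorm(17)
  expect_equal(temporalConvolution(g, 1), g)   # identity kernel
  expect_error(temporalConvolution(c(1, 2), c(1, 1, 1)),
               "n=2.*k=3")
})

test_that("temporal convolution matches the brute-force double loop", {
  set.seed(21)
  for (i in 1:200) {
    k <- sample(1:8, 1); d <- sample(1:k, 1)
    n <- k + sample(0:40, 1)
    g <- rnorm(n); f <- rnorm(k)
    expect_equal(temporalConvolution(g, f, d), bruteConv(g, f, d),
                 tolerance = 1e-12)
  }
})

test_that("temporal max-pooling reproduces worked examples and the oracle", {
  expect_equal(temporalMaxPool(c(1, 3, 2, 5), 2, 2), c(3, 5))
  expect_equal(temporalMaxPool(c(7, 7, 7), 3, 1), 7)
  expect_error(temporalMaxPool(c(1, 2), 3), "n=2.*k=3")
  set.seed(22)
  for (i in 1:200) {
    k <- sample(1:8, 1); d <- sample(1:k, 1)
    n <- k + sample(0:40, 1)
    g <- rnorm(n)
    expect_equal(temporalMaxPool(g, k, d), brutePool(g, k, d),
                 tolerance = 1e-12)
  }
})

test_that("convolution is linear and pooling is monotone", {
  set.seed(23)
  for (i in 1:25) {
    k <- sample(2:6, 1); d <- sample(1:k, 1); n <- k + sample(1:30, 1)
    f <- rnorm(k); g1 <- rnorm(n); g2 <- rnorm(n)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(temporalConvolution(a * g1 + b * g2, f, d),
                 a * temporalConvolution(g1, f, d) +
                   b * temporalConvolution(g2, f, d), tolerance = 1e-9)
    lo <- pmin(g1, g2); hi <- pmax(g1, g2)
    expect_true(all(temporalMaxPool(lo, k, d) <= temporalMaxPool(hi, k, d)))
  }
})

test_that("the batched C++ conv layer computes the same sum as the R operator", {
  set.seed(24)
  # single channel: one kernel, layout coincides with f(1..k)
  for (i in 1:20) {
    k <- sample(1:6, 1); d <- sample(1:k, 1); n <- k + sample(0:30, 1)
    g <- rnorm(n); f <- rnorm(k)
    out <- barcodeCNN:::cnn_conv_layer_cpp(matrix(g, 1), matrix(f, 1), 0, k, d)
    expect_equal(as.numeric(out), temporalConvolution(g, f, d),
                 tolerance = 1e-12)
  }
  # multi-channel: layer output is the sum of per-channel convolutions
  ch <- 3; k <- 4; n <- 21
  G <- matrix(rnorm(ch * n), ch)
  W <- matrix(rnorm(ch * k), 1)       # column px*ch + ic
  out <- barcodeCNN:::cnn_conv_layer_cpp(G, W, 0, k, 1L)
  manual <- Reduce(`+`, lapply(seq_len(ch), function(ic) {
    f <- W[1, (seq_len(k) - 1) * ch + ic]
    temporalConvolution(G[ic, ], f, 1L)
  }))
  expect_equal(as.numeric(out), manual, tolerance = 1e-12)
})

test_that("stage lengths follow the floor((n-k)/d)+1 algebra", {
  crepeLike <- modelConfig(frameLength = 258L, dictSize = 125L, nClasses = 9L,
                           convFeatures = rep(64L, 6L),
                           convKernels = c(7L, 7L, 3L, 3L, 3L, 3L),
                           convStrides = rep(1L, 6L),
                           poolWidths = c(3L, 3L, 0L, 0L, 0L, 3L),
                           fcWidths = c(256L, 256L), dropout = 0.5)
  tr <- featureTrace(crepeLike)
  # hand-traced chain
  expect_identical(tr$length,
                   c(258L, 252L, 84L, 78L, 26L, 24L, 22L, 20L, 18L, 6L))
  expect_error(modelConfig(frameLength = 30L, dictSize = 125L, nClasses = 9L,
                           convFeatures = rep(64L, 6L),
                           convKernels = c(7L, 7L, 3L, 3L, 3L, 3L),
                           convStrides = rep(1L, 6L),
                           poolWidths = c(3L, 3L, 0L, 0L, 0L, 3L),
                           fcWidths = c(256L, 256L)),
               "layer")
  set.seed(25)
  for (i in 1:20) {
    n <- sample(20:200, 1); k <- sample(1:7, 1); d <- sample(1:k, 1)
    expect_identical(convOutputLength(n, k, d),
                     as.integer(floor((n - k) / d) + 1))
  }
})

test_that("global pooling resolves NA pool widths against the stack", {
  cfg <- modelConfig()
  tr <- featureTrace(cfg)
  expect_identical(tr$length[nrow(tr)], 1L)
  expect_identical(cfg$poolWidths, 254L)   # 258 - 5 + 1
})

test_that("model building is seed-deterministic", {
  m1 <- buildModel(smallModel(seed = 77))
  m2 <- buildModel(smallModel(seed = 77))
  m3 <- buildModel(smallModel(seed = 78))
  expect_identical(m1@params, m2@params)
  expect_false(identical(m1@params, m3@params))
})

test_that("prediction returns a probability simplex with first-index ties", {
  mc <- smallModel(C = 4, L = 10)
  m <- buildModel(mc)
  set.seed(26)
  frames <- array(0L, dim = c(125, 10, 32))
  for (i in 1:32) frames[, , i] <- quantizeFrame(sample(0:124, 8),
                                                 frameLength = 10, D = 125)
  pr <- predict(m, frames)
  expect_identical(dim(pr$scores), c(32L, 4L))
  expect_true(all(pr$scores >= 0))
  expect_equal(rowSums(pr$scores), rep(1, 32), tolerance = 1e-6)

  one <- lapply(1:32, function(i) predict(m, frames[, , i]))
  expect_identical(vapply(one, `[[`, 0L, "label"), pr$label)

  # zero-initialized output: exact symmetry, uniform scores, tie to class 1
  z <- buildModel(modelConfig(frameLength = 10, dictSize = 125, nClasses = 4,
                              convFeatures = 8L, convKernels = 3L,
                              convStrides = 1L, poolWidths = NA_integer_,
                              fcWidths = 8L, initScale = 0, dropout = 0))
  przero <- predict(z, frames[, , 1])
  expect_equal(as.numeric(przero$scores), rep(0.25, 4), tolerance = 1e-12)
  expect_identical(przero$label, 1L)
})

test_that("shape mismatches are reported with the expected dimensions", {
  m <- buildModel(smallModel(C = 2, L = 10))
  expect_error(predict(m, matrix(0, 7, 10)), "expected \\(125, 10\\)")
  expect_error(predict(m, matrix(c(1, 1), 125, 10)), "one-hot")
})

test_that("checkpoints round trip and refuse unknown versions", {
  m <- buildModel(smallModel())
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@params, m@params)
  expect_identical(m2@config, m@config)
  x <- readRDS(path); x$version <- "v999"; saveRDS(x, path)
  expect_error(loadModel(path), "version")
})
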