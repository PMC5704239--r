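test_that("the learning-rate schedule halves every period", {
  r <- 0.01
  expect_equal(lrSchedule(r, 9, 3),
               c(r, r, r, r / 2, r / 2, r / 2, r / 4, r / 4, r / 4))
  expect_equal(lrSchedule(1, 4, 10), rep(1, 4))
})

test_that("training is deterministic in the seed", {
  toy <- separableToySet(perClass = 12)
  parts <- splitDataset(toy, splitSpec(0.7, 0.3, 0, seed = 1))
  mc <- smallModel(C = 2, L = 20)
  tc <- trainConfig(epochs = 3, batchSize = 4, lr = 1e-3, seed = 9,
                    mode = "encoded")
  f1 <- trainClassifier(buildModel(mc), parts$train, parts$cv, tc)
  f2 <- trainClassifier(buildModel(mc), parts$train, parts$cv, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
  tc2 <- trainConfig(epochs = 3, batchSize = 4, lr = 1e-3, seed = 10,
                     mode = "encoded")
  f3 <- trainClassifier(buildModel(mc), parts$train, parts$cv, tc2)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("a linearly separable two-class problem is learned perfectly", {
  toy <- separableToySet(perClass = 24)
  parts <- splitDataset(toy, splitSpec(0.6, 0.4, 0, seed = 4))
  mc <- smallModel(C = 2, L = 20, seed = 4)
  tc <- trainConfig(epochs = 20, batchSize = 4, lr = 1e-2, seed = 4,
                    mode = "encoded")
  fit <- trainClassifier(buildModel(mc), parts$train, parts$cv, tc)
  expect_equal(max(fit$history$cvAccuracy), 1.0)
  # and momentum SGD learns it too
  tcs <- trainConfig(epochs = 20, batchSize = 4, lr = 0.05,
                     lrHalvePeriod = 10, seed = 4, mode = "encoded",
                     optimizer = "sgd")
  fits <- trainClassifier(buildModel(mc), parts$train, parts$cv, tcs)
  expect_gte(max(fits$history$cvAccuracy), 0.9)
})

test_that("training rejects empty or mislabelled inputs", {
  toy <- separableToySet(perClass = 4)
  mc <- smallModel(C = 2, L = 20)
  expect_error(trainClassifier(buildModel(mc), toy[integer(0)], toy,
                               trainConfig(epochs = 1)), "empty")
  bad <- BarcodeSeqSet(as.character(barcodeSequences(toy)),
                       rep(c(1L, 3L), length(toy) / 2),
                       data.frame(order = c("a", "b", "c"), label = 1:3))
  expect_error(trainClassifier(buildModel(mc), bad, toy,
                               trainConfig(epochs = 1)), "out of range")
  expect_error(trainClassifier(buildModel(smallModel(D = 5)), toy, toy,
                               trainConfig(epochs = 1, mode = "encoded")),
               "dictSize")
})

test_that("evaluation tabulates true against predicted labels exactly", {
  toy <- separableToySet(perClass = 16)
  mc <- smallModel(C = 2, L = 20, seed = 2)
  tc <- trainConfig(epochs = 20, batchSize = 4, lr = 1e-2, seed = 2,
                    mode = "encoded")
  fit <- trainClassifier(buildModel(mc), toy, toy, tc)
  cm <- evaluateModel(fit$bestModel, toy, tc)
  expect_identical(sum(cm), 32L)
  expect_identical(dim(cm), c(2L, 2L))
  # a learner that solved the toy gives a diagonal matrix
  expect_identical(sum(diag(cm)), 32L)

  # constant predictor: zero-initialized network always answers class 1
  z <- buildModel(smallModel(C = 2, L = 20))
  z@params$out$W[] <- 0; z@params$out$b[] <- 0
  z@params$fc[[1]]$W[] <- 0
  cmz <- evaluateModel(z, toy, tc)
  expect_identical(as.integer(colSums(cmz)), c(32L, 0L))

  # counting conservation for an arbitrary predictor on random labels
  set.seed(6)
  rnd <- BarcodeSeqSet(vapply(rep(30, 40), randomCleanSeq, ""),
                       sample(1:2, 40, replace = TRUE))
  expect_identical(sum(evaluateModel(z, rnd, tc)), 40L)
})

test_that("metrics agree with direct counting on worked and random matrices", {
  r <- classifierMetrics(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(r$accuracy, 1); expect_equal(r$macroRecall, 1)
  expect_equal(r$macroPrecision, 1)

  cm <- matrix(c(3, 1, 2, 4), 2, byrow = TRUE)
  m <- classifierMetrics(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(unname(m$recall), c(0.75, 2 / 3))
  expect_equal(unname(m$precision), c(0.6, 0.8))
  expect_equal(m$macroRecall, (0.75 + 2 / 3) / 2)
  expect_equal(m$macroPrecision, 0.7)

  set.seed(27)
  for (i in 1:50) {
    C <- sample(2:9, 1)
    cm <- matrix(rpois(C * C, 3), C)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- suppressWarnings(classifierMetrics(cm))
    want <- bruteMetrics(cm)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(unname(got$recall), want$recall, tolerance = 1e-12)
    expect_equal(unname(got$precision), want$precision, tolerance = 1e-12)
    expect_equal(got$macroRecall, want$macroRecall, tolerance = 1e-12)
    expect_equal(got$macroPrecision, want$macroPrecision, tolerance = 1e-12)
    # accuracy is the micro-averaged recall
    expect_equal(got$accuracy,
                 sum(diag(cm)) / sum(rowSums(cm)), tolerance = 1e-12)
  }
})

test_that("degenerate classes warn and score zero instead of dropping", {
  cm <- matrix(c(4, 0, 1, 0, 0, 3, 0, 0, 2), 3, byrow = TRUE)
  expect_warning(m <- classifierMetrics(cm), "never predicted")
  expect_equal(unname(m$precision[2]), 0)
  expect_length(m$recall, 3)
  cm2 <- matrix(c(2, 1, 0, 0, 3, 0, 0, 0, 0), 3, byrow = TRUE)
  w <- testthat::capture_warnings(m2 <- classifierMetrics(cm2))
  expect_true(any(grepl("no true samples", w)))
  expect_true(any(grepl("never predicted", w)))
  expect_equal(unname(m2$recall[3]), 0)
  expect_error(classifierMetrics(matrix(0, 2, 2)), "all-zero")
})

test_that("reports and confusion matrices are written as documented", {
  cm <- confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2), C = 2)
  expect_identical(unname(cm["1", "2"]), 1L)
  rp <- tempfile(); cf <- tempfile()
  writeMetricsReport(suppressWarnings(classifierMetrics(cm)), rp)
  txt <- readLines(rp)
  expect_true(any(grepl("^accuracy = 0.75", txt)))
  expect_true(any(grepl("^macro_recall = ", txt)))
  writeConfusionMatrix(cm, cf)
  back <- utils::read.csv(cf, check.names = FALSE)
  expect_identical(as.integer(as.matrix(back[, -1])), as.integer(cm))
})
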