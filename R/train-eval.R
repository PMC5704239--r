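#' Training configuration
#'
#' Hyperparameters of the mini-batch gradient descent loop: negative
#' log-likelihood loss on the softmax output and a step learning-rate
#' schedule that halves the rate every \code{lrHalvePeriod} epochs. Two
#' optimizers are available: classic momentum SGD (the recipe of the large
#' character-level text CNNs: momentum 0.9, rate 0.01, halving every 3
#' epochs, batches of 32) and Adam, the default, whose per-parameter step
#' scaling reaches the planted-motif signal within a desk-scale update
#' budget where plain SGD stays on its initial plateau (see the vignette).
#' There is no early stopping; the loop runs the fixed number of epochs and
#' the checkpoint with the best cross-validation accuracy is retained
#' alongside the final one.
#'
#' @param epochs Number of passes over the training subset.
#' @param batchSize Mini-batch size.
#' @param lr Initial learning rate.
#' @param momentum Momentum coefficient.
#' @param lrHalvePeriod Epochs between halvings of the learning rate.
#' @param seed Seed driving shuffling and dropout; equal seeds give equal
#'   loss histories.
#' @param mode \code{"encoded"} (3-1 codon tokens, D = 125) or \code{"raw"}
#'   (single-character tokens, D = 5).
#' @param order Frame quantization order, see [quantizeFrame()].
#' @param optimizer \code{"sgd"} (momentum SGD, the classic recipe) or
#'   \code{"adam"} (adaptive moments; far fewer updates to escape the
#'   feature-learning plateau on small datasets, see the vignette). With
#'   \code{"adam"}, \code{lr} is the Adam step size (0.001 is a good
#'   default) and \code{momentum} is ignored.
#' @return Validated list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(epochs = 20L, batchSize = 8L, lr = 0.002,
                        momentum = 0.9, lrHalvePeriod = 10L, seed = 1L,
                        mode = c("encoded", "raw"),
                        order = c("forward", "reverse"),
                        optimizer = c("adam", "sgd")) {
  mode <- match.arg(mode); order <- match.arg(order)
  optimizer <- match.arg(optimizer)
  vals <- c(epochs = epochs, batchSize = batchSize, lr = lr,
            momentum = momentum, lrHalvePeriod = lrHalvePeriod)
  if (any(vals[c("epochs", "batchSize", "lr", "lrHalvePeriod")] <= 0))
    stop("epochs, batchSize, lr and lrHalvePeriod must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr = lr,
                 momentum = momentum,
                 lrHalvePeriod = as.integer(lrHalvePeriod),
                 seed = as.integer(seed), mode = mode, order = order,
                 optimizer = optimizer),
            class = "trainConfig")
}

#' Dictionary implied by an encoding mode
#'
#' @param mode \code{"encoded"} (k = 3) or \code{"raw"} (k = 1).
#' @return A [CodonDictionary-class].
#' @export
modeDictionary <- function(mode = c("encoded", "raw")) {
  mode <- match.arg(mode)
  buildDictionary(barcodeAlphabet(), if (mode == "encoded") 3L else 1L)
}

#' Per-epoch learning-rate schedule
#'
#' @param lr0 Initial rate.
#' @param epochs Number of epochs.
#' @param period Halving period.
#' @return Numeric vector: \code{lr0 / 2^floor((epoch-1)/period)}.
#' @export
lrSchedule <- function(lr0, epochs, period) {
  lr0 / 2^((seq_len(epochs) - 1L) %/% period)
}

## elementwise map over the fixed param structure
.mapParams <- function(f, ...) {
  args <- list(...)
  mapLayer <- function(...) {
    ls <- list(...)
    list(W = do.call(f, lapply(ls, `[[`, "W")),
         b = do.call(f, lapply(ls, `[[`, "b")))
  }
  list(conv = do.call(Map, c(list(mapLayer), lapply(args, `[[`, "conv"))),
       fc   = do.call(Map, c(list(mapLayer), lapply(args, `[[`, "fc"))),
       out  = do.call(mapLayer, lapply(args, `[[`, "out")))
}

.predictTokens <- function(params, tok, cppCfg) {
  probs <- cnn_predict_cpp(params, tok, cppCfg)
  list(label = max.col(probs, ties.method = "first"), scores = probs)
}

#' Train the classifier
#'
#' Runs mini-batch SGD with momentum over the (sanitized, tokenized,
#' framed) training records, evaluating cross-validation accuracy after each
#' epoch. All randomness (shuffling, dropout masks) comes from the R RNG
#' seeded by \code{cfg$seed}, so two runs with equal inputs and seeds
#' produce identical histories and parameters.
#'
#' @param model A freshly built (or resumed) [CNNClassifier-class]; its
#'   \code{dictSize} must match the mode's dictionary.
#' @param trainSet,cvSet [BarcodeSeqSet-class] subsets from
#'   [splitDataset()].
#' @param cfg A [trainConfig()].
#' @param verbose Print a per-epoch log line (epoch, lr, loss, cv accuracy).
#' @return List with \code{model} (final), \code{bestModel} (highest cv
#'   accuracy checkpoint), and \code{history} (\code{data.frame} with
#'   \code{epoch}, \code{lr}, \code{loss}, \code{cvAccuracy}).
#' @export
trainClassifier <- function(model, trainSet, cvSet, cfg = trainConfig(),
                            verbose = FALSE) {
  stopifnot(is(model, "CNNClassifier"), inherits(cfg, "trainConfig"))
  if (length(trainSet) == 0L) stop("training set is empty")
  mcfg <- model@config
  dict <- modeDictionary(cfg$mode)
  if (dictionarySize(dict) != mcfg$dictSize)
    stop(sprintf("model dictSize %d does not match mode '%s' (D = %d)",
                 mcfg$dictSize, cfg$mode, dictionarySize(dict)))
  C <- mcfg$nClasses
  yTr <- seqLabels(trainSet); yCv <- seqLabels(cvSet)
  badLab <- which(yTr < 1L | yTr > C)
  if (length(badLab))
    stop("training label out of range 1..", C, " for record '",
         names(trainSet)[badLab[1]], "'")
  tokTr <- tokenMatrix(trainSet, dict, mcfg$frameLength, cfg$order)
  tokCv <- if (length(cvSet)) tokenMatrix(cvSet, dict, mcfg$frameLength,
                                          cfg$order) else NULL
  cppCfg <- .cppConfig(mcfg)
  params <- model@params
  vel <- .mapParams(function(w) w * 0, params)
  adamM <- vel; adamV <- vel; adamT <- 0L
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  nTr <- length(trainSet)
  useDrop <- mcfg$dropout > 0 && length(mcfg$fcWidths) > 0
  hist <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, params = params)
  lrs <- lrSchedule(cfg$lr, cfg$epochs, cfg$lrHalvePeriod)
  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lrE <- lrs[epoch]
      perm <- sample.int(nTr)
      starts <- seq(1L, nTr, by = cfg$batchSize)
      lossSum <- 0
      for (s0 in starts) {
        idx <- perm[s0:min(s0 + cfg$batchSize - 1L, nTr)]
        nb <- length(idx)
        masks <- if (useDrop) {
          lapply(mcfg$fcWidths, function(w)
            matrix((runif(w * nb) >= mcfg$dropout) / (1 - mcfg$dropout),
                   nrow = w))
        } else list()
        res <- cnn_batch_grad_cpp(params, tokTr[, idx, drop = FALSE],
                                  yTr[idx], cppCfg, masks)
        lossSum <- lossSum + res$loss * nb
        if (cfg$optimizer == "sgd") {
          vel <- .mapParams(function(v, g) cfg$momentum * v - lrE * g,
                            vel, res$grads)
          params <- .mapParams(`+`, params, vel)
        } else {
          adamT <- adamT + 1L
          adamM <- .mapParams(function(m, g) b1 * m + (1 - b1) * g,
                              adamM, res$grads)
          adamV <- .mapParams(function(v, g) b2 * v + (1 - b2) * g^2,
                              adamV, res$grads)
          corr <- sqrt(1 - b2^adamT) / (1 - b1^adamT)
          params <- .mapParams(function(p, m, v)
            p - lrE * corr * m / (sqrt(v) + adamEps),
            params, adamM, adamV)
        }
      }
      cvAcc <- if (is.null(tokCv)) NA_real_ else
        mean(.predictTokens(params, tokCv, cppCfg)$label == yCv)
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lrE,
                                  loss = lossSum / nTr, cvAccuracy = cvAcc)
      if (!is.na(cvAcc) && cvAcc > best$acc)
        best <- list(acc = cvAcc, params = params)
      if (verbose)
        message(sprintf("epoch %2d  lr %.5f  loss %.4f  cv acc %s",
                        epoch, lrE, lossSum / nTr,
                        ifelse(is.na(cvAcc), "NA", sprintf("%.4f", cvAcc))))
    }
  })
  final <- model; final@params <- params
  bestM <- model
  bestM@params <- if (is.finite(best$acc)) best$params else params
  list(model = final, bestModel = bestM, history = do.call(rbind, hist))
}

#' Evaluate a classifier into a confusion matrix
#'
#' Applies the model's encoding pipeline (sanitize, tokenize, frame) to the
#' records and tabulates true against predicted labels. Rows are true
#' classes, columns predicted classes; the total count equals the number of
#' records.
#'
#' @param model A [CNNClassifier-class].
#' @param records A [BarcodeSeqSet-class].
#' @param cfg A [trainConfig()] naming the encoding mode and frame order
#'   used at training time.
#' @param batchSize Prediction batch size.
#' @return Integer \code{C x C} matrix with dimnames \code{true} /
#'   \code{predicted}.
#' @export
evaluateModel <- function(model, records, cfg = trainConfig(),
                          batchSize = 256L) {
  stopifnot(is(model, "CNNClassifier"))
  dict <- modeDictionary(cfg$mode)
  mcfg <- model@config
  if (dictionarySize(dict) != mcfg$dictSize)
    stop(sprintf("model dictSize %d does not match mode '%s' (D = %d)",
                 mcfg$dictSize, cfg$mode, dictionarySize(dict)))
  tok <- tokenMatrix(records, dict, mcfg$frameLength, cfg$order)
  cppCfg <- .cppConfig(mcfg)
  n <- length(records)
  pred <- integer(n)
  for (s0 in seq(1L, n, by = batchSize)) {
    idx <- s0:min(s0 + batchSize - 1L, n)
    pred[idx] <- .predictTokens(model@params, tok[, idx, drop = FALSE],
                                cppCfg)$label
  }
  confusionMatrix(seqLabels(records), pred, mcfg$nClasses)
}

#' Build a confusion matrix from label vectors
#'
#' @param true,predicted Integer label vectors in \code{1..C}.
#' @param C Number of classes.
#' @return Integer \code{C x C} matrix, rows = true, columns = predicted.
#' @export
confusionMatrix <- function(true, predicted, C = max(true, predicted)) {
  stopifnot(length(true) == length(predicted))
  cm <- table(factor(true, levels = seq_len(C)),
              factor(predicted, levels = seq_len(C)))
  m <- matrix(as.integer(cm), C, C,
              dimnames = list(true = seq_len(C), predicted = seq_len(C)))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total count ("true predictions divided by
#' the total number of predictions"); per-class recall (sensitivity) divides
#' each diagonal entry by its row total, per-class precision by its column
#' total; macro recall / precision are the unweighted means over all
#' classes. A class with an empty row (no true samples) or empty column
#' (never predicted) contributes 0 to the corresponding macro average and
#' raises a warning rather than being dropped, keeping the averages defined
#' and conservative.
#'
#' @param cm A square confusion matrix (rows true, columns predicted).
#' @return List of class \code{"metricsReport"} with \code{accuracy},
#'   \code{recall}, \code{precision} (per-class vectors),
#'   \code{macroRecall}, \code{macroPrecision} and \code{n} (total count).
#' @examples
#' classifierMetrics(matrix(c(5, 0, 0, 5), 2))$accuracy  # 1
#' @export
classifierMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is all-zero")
  rowTot <- rowSums(cm); colTot <- colSums(cm)
  if (any(rowTot == 0))
    warning("class(es) with no true samples score recall 0: ",
            paste(which(rowTot == 0), collapse = ", "))
  if (any(colTot == 0))
    warning("class(es) never predicted score precision 0: ",
            paste(which(colTot == 0), collapse = ", "))
  rec <- ifelse(rowTot > 0, diag(cm) / rowTot, 0)
  prec <- ifelse(colTot > 0, diag(cm) / colTot, 0)
  structure(list(accuracy = sum(diag(cm)) / total,
                 recall = rec, precision = prec,
                 macroRecall = mean(rec), macroPrecision = mean(prec),
                 n = total),
            class = "metricsReport")
}

#' @export
print.metricsReport <- function(x, ...) {
  cat(sprintf("accuracy        = %.6f\n", x$accuracy))
  cat(sprintf("macro_recall    = %.6f\n", x$macroRecall))
  cat(sprintf("macro_precision = %.6f\n", x$macroPrecision))
  cat(sprintf("n               = %d\n", as.integer(x$n)))
  invisible(x)
}

#' Write a metrics report / confusion matrix to disk
#'
#' The report is written as \code{key = value} lines (per-class values
#' comma-separated); the confusion matrix as CSV with a leading header row
#' and column of class labels.
#'
#' @param report A \code{metricsReport} from [classifierMetrics()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  fmt <- function(v) paste(format(v, digits = 6, trim = TRUE), collapse = ",")
  writeLines(c(
    sprintf("accuracy = %s", fmt(report$accuracy)),
    sprintf("macro_recall = %s", fmt(report$macroRecall)),
    sprintf("macro_precision = %s", fmt(report$macroPrecision)),
    sprintf("recall = %s", fmt(report$recall)),
    sprintf("precision = %s", fmt(report$precision)),
    sprintf("n = %d", as.integer(report$n))), path)
  invisible(path)
}

#' @rdname writeMetricsReport
#' @param cm A confusion matrix.
#' @export
writeConfusionMatrix <- function(cm, path) {
  df <- data.frame(true = rownames(cm), as.data.frame.matrix(cm),
                   check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
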