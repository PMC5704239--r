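#' Temporal convolution of a 1D signal
#'
#' The model's core operator: the discrete 1D convolution
#' \deqn{h(y) = \sum_{x=1}^{k} f(x) \, g(y d - x + c), \qquad y = 1..m,}
#' with kernel width \eqn{k}, stride \eqn{d} and offset constant
#' \eqn{c = k - d + 1}, the only convention under which the index
#' \eqn{y d - x + c} stays inside \eqn{1..n} for every stride. The output
#' length is \eqn{m = \lfloor (n-k)/d \rfloor + 1}. Note the kernel is
#' traversed in reverse over each window (true convolution, not
#' cross-correlation).
#'
#' @param g Numeric vector, the input signal \eqn{g(1..n)}.
#' @param kernel Numeric vector, the kernel \eqn{f(1..k)}.
#' @param stride Positive integer stride \eqn{d \le k}.
#' @return Numeric vector \eqn{h(1..m)}.
#' @examples
#' temporalConvolution(c(1, 2, 3, 4), c(1, 1))  # 3 5 7
#' @export
temporalConvolution <- function(g, kernel, stride = 1L) {
  n <- length(g); k <- length(kernel); d <- as.integer(stride)
  if (k < 1L) stop("kernel must be non-empty")
  if (d < 1L || d > k) stop("stride must satisfy 1 <= d <= k")
  if (n < k)
    stop(sprintf("input length n=%d is shorter than kernel width k=%d", n, k))
  cc <- k - d + 1L
  m <- (n - k) %/% d + 1L
  vapply(seq_len(m), function(y) sum(kernel * g[y * d - seq_len(k) + cc]),
         numeric(1))
}

#' Temporal max-pooling of a 1D signal
#'
#' The 1D analogue of spatial max-pooling:
#' \deqn{h(y) = \max_{x=1..k} g(y d - x + c), \qquad c = k - d + 1,}
#' over the same index windows as [temporalConvolution()]; output length
#' \eqn{\lfloor (n-k)/d \rfloor + 1}.
#'
#' @param g Numeric input signal.
#' @param width Pooling window width \eqn{k}.
#' @param stride Stride \eqn{d} (defaults to \code{width}: non-overlapping
#'   pooling).
#' @return Numeric vector of window maxima.
#' @examples
#' temporalMaxPool(c(1, 3, 2, 5), 2)  # 3 5
#' @export
temporalMaxPool <- function(g, width, stride = width) {
  n <- length(g); k <- as.integer(width); d <- as.integer(stride)
  if (k < 1L || d < 1L || d > k) stop("need 1 <= stride <= width")
  if (n < k)
    stop(sprintf("input length n=%d is shorter than pool width k=%d", n, k))
  cc <- k - d + 1L
  m <- (n - k) %/% d + 1L
  vapply(seq_len(m), function(y) max(g[y * d - seq_len(k) + cc]), numeric(1))
}

#' Output length of a temporal stage
#'
#' @param n Input length.
#' @param k Kernel or pool width.
#' @param d Stride.
#' @return \eqn{\lfloor (n-k)/d \rfloor + 1}.
#' @export
convOutputLength <- function(n, k, d = 1L) (n - k) %/% d + 1L

#' Model architecture configuration
#'
#' Describes the character-level CNN: a stack of temporal-convolution
#' blocks (each optionally followed by non-overlapping max-pooling) over the
#' one-hot frame, flattened into fully-connected layers ending in a C-way
#' softmax. The default is a motif-scanner network sized for desk-scale
#' barcode data: one bank of 128 width-5 convolution kernels over the
#' codon-token frame, global temporal max-pooling (each feature reports its
#' strongest match anywhere in the sequence, making the representation
#' position-invariant), and one width-64 fully-connected layer before the
#' 9-way softmax. Deeper text-CNN-style stacks with local pooling can be
#' configured through the same interface; the vignette discusses why the
#' shallow global-pooling default trains reliably at small sample sizes
#' where deep stacks do not.
#'
#' @param frameLength Frame length L (token positions).
#' @param dictSize Number of one-hot rows D (dictionary symbols).
#' @param nClasses Number of classes C.
#' @param convFeatures,convKernels,convStrides Integer vectors, one entry
#'   per convolution layer.
#' @param poolWidths Integer vector per layer; 0 disables pooling after that
#'   layer, \code{NA} pools globally (width = the full feature length at
#'   that stage).
#' @param poolStrides Pooling strides; defaults to \code{poolWidths}
#'   (non-overlapping).
#' @param fcWidths Widths of the hidden fully-connected layers.
#' @param dropout Dropout probability on fully-connected activations during
#'   training (inverted dropout; inference needs no rescaling).
#' @param initScale Standard deviation of the zero-mean Gaussian weight
#'   initialization. \code{NULL} (default) uses the per-layer scale
#'   \code{sqrt(2 / fanIn)}; a numeric value is applied to every layer
#'   (0 gives a zero-initialized network).
#' @param activation Nonlinearity; only \code{"relu"} (thresholded linear)
#'   is implemented.
#' @param seed Integer seed for parameter initialization.
#' @return Validated configuration list of class \code{"modelConfig"}.
#' @examples
#' cfg <- modelConfig()
#' featureTrace(cfg)
#' @export
modelConfig <- function(frameLength = 258L, dictSize = 125L, nClasses = 9L,
                        convFeatures = 128L,
                        convKernels = 5L,
                        convStrides = 1L,
                        poolWidths = NA_integer_,
                        poolStrides = NULL,
                        fcWidths = 64L,
                        dropout = 0, initScale = NULL,
                        activation = "relu", seed = 1L) {
  nl <- length(convFeatures)
  if (length(convKernels) != nl || length(convStrides) != nl ||
      length(poolWidths) != nl)
    stop("convFeatures, convKernels, convStrides and poolWidths must have one entry per layer")
  ## resolve NA pool widths (global pooling) against the length algebra
  poolWidths <- as.integer(poolWidths)
  n <- as.integer(frameLength)
  for (i in seq_len(nl)) {
    if (n >= convKernels[i])
      n <- convOutputLength(n, as.integer(convKernels[i]),
                            as.integer(convStrides[i]))
    if (is.na(poolWidths[i])) poolWidths[i] <- n
    if (poolWidths[i] > 0L && n >= poolWidths[i])
      n <- convOutputLength(n, poolWidths[i], poolWidths[i])
  }
  if (is.null(poolStrides)) poolStrides <- poolWidths
  if (!identical(activation, "relu"))
    stop("only the 'relu' activation is implemented")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  cfg <- list(frameLength = as.integer(frameLength),
              dictSize = as.integer(dictSize),
              nClasses = as.integer(nClasses),
              convFeatures = as.integer(convFeatures),
              convKernels = as.integer(convKernels),
              convStrides = as.integer(convStrides),
              poolWidths = as.integer(poolWidths),
              poolStrides = as.integer(poolStrides),
              fcWidths = as.integer(fcWidths),
              dropout = as.numeric(dropout),
              initScale = if (is.null(initScale)) NULL else as.numeric(initScale),
              activation = activation,
              seed = as.integer(seed))
  class(cfg) <- "modelConfig"
  featureTrace(cfg)   # validates length algebra, errors on underflow
  cfg
}

#' Trace the feature length through the stack
#'
#' Applies the output-length rule \eqn{m = \lfloor (n-k)/d \rfloor + 1} to
#' every convolution and pooling stage, erroring (with the offending layer
#' and the minimum frame length that would survive) if any stage underflows.
#'
#' @param config A [modelConfig()].
#' @return \code{data.frame} with one row per stage: stage label, kernel,
#'   stride and output length. The last row's length is the final feature
#'   length.
#' @export
featureTrace <- function(config) {
  minLenFrom <- function(stages) {
    need <- 1L
    for (s in rev(stages)) need <- (need - 1L) * s[2] + s[1]
    need
  }
  n <- config$frameLength
  rows <- list(list(stage = "input", k = NA_integer_, d = NA_integer_,
                    length = n))
  allStages <- list()
  for (i in seq_along(config$convFeatures)) {
    for (what in c("conv", "pool")) {
      k <- if (what == "conv") config$convKernels[i] else config$poolWidths[i]
      d <- if (what == "conv") config$convStrides[i] else config$poolStrides[i]
      if (what == "pool" && k == 0L) next
      allStages <- c(allStages, list(c(k, d)))
      if (n < k)
        stop(sprintf(
          "layer %d (%s, width %d): feature length underflow (have %d); frame length must be at least %d",
          i, what, k, n, minLenFrom(allStages)))
      n <- convOutputLength(n, k, d)
      rows <- c(rows, list(list(stage = sprintf("%s%d", what, i), k = k,
                                d = d, length = n)))
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

.MODEL_VERSION <- "barcodeCNN-model-v1"

## cfg list in the exact shape the C++ routines expect
.cppConfig <- function(config) {
  list(D = config$dictSize, L = config$frameLength, C = config$nClasses,
       convFeatures = config$convFeatures, convKernels = config$convKernels,
       convStrides = config$convStrides, poolWidths = config$poolWidths,
       poolStrides = config$poolStrides, fcWidths = config$fcWidths,
       dropout = config$dropout)
}

#' Build (initialize) a CNN classifier
#'
#' Allocates and seeds the parameters of every layer described by the
#' configuration. Weights are zero-mean Gaussian (see
#' \code{initScale} in [modelConfig()]), biases zero; the draw order is
#' fixed, so equal seeds give bit-identical parameters.
#'
#' @param config A [modelConfig()].
#' @return A [CNNClassifier-class].
#' @examples
#' m <- buildModel(modelConfig(frameLength = 60, nClasses = 3,
#'   convFeatures = 8, convKernels = 5, convStrides = 1, poolWidths = 3,
#'   fcWidths = 16))
#' m
#' @export
buildModel <- function(config) {
  tr <- featureTrace(config)
  finalLen <- tr$length[nrow(tr)]
  sdFor <- function(fanIn)
    if (is.null(config$initScale)) sqrt(2 / fanIn) else config$initScale
  params <- withSeed(config$seed, {
    inCh <- config$dictSize
    conv <- vector("list", length(config$convFeatures))
    for (i in seq_along(conv)) {
      fanIn <- inCh * config$convKernels[i]
      conv[[i]] <- list(
        W = matrix(rnorm(config$convFeatures[i] * fanIn, 0, sdFor(fanIn)),
                   nrow = config$convFeatures[i]),
        b = numeric(config$convFeatures[i]))
      inCh <- config$convFeatures[i]
    }
    inW <- inCh * finalLen
    fc <- vector("list", length(config$fcWidths))
    for (i in seq_along(fc)) {
      fc[[i]] <- list(W = matrix(rnorm(config$fcWidths[i] * inW, 0, sdFor(inW)),
                                 nrow = config$fcWidths[i]),
                      b = numeric(config$fcWidths[i]))
      inW <- config$fcWidths[i]
    }
    out <- list(W = matrix(rnorm(config$nClasses * inW, 0, sdFor(inW)),
                           nrow = config$nClasses),
                b = numeric(config$nClasses))
    list(conv = conv, fc = fc, out = out)
  })
  new("CNNClassifier", config = unclass(config), params = params,
      seed = config$seed, version = .MODEL_VERSION)
}

setMethod("show", "CNNClassifier", function(object) {
  cfg <- object@config
  tr <- featureTrace(structure(cfg, class = "modelConfig"))
  np <- sum(rapply(object@params, length, how = "unlist"))
  cat(sprintf("CNNClassifier: %d-class, frame %dx%d\n",
              cfg$nClasses, cfg$dictSize, cfg$frameLength))
  cat(sprintf("  conv layers: %s (final feature length %d)\n",
              paste(sprintf("%dx%d", cfg$convFeatures, cfg$convKernels),
                    collapse = " "), tr$length[nrow(tr)]))
  cat(sprintf("  fully connected: %s -> %d classes; %d parameters; seed %d\n",
              paste(cfg$fcWidths, collapse = " "), cfg$nClasses,
              as.integer(np), object@seed))
})

## tokens from a one-hot frame (columns must sum to 0 or 1)
.frameTokens <- function(frame, D, L) {
  if (nrow(frame) != D || ncol(frame) != L)
    stop(sprintf("frame shape mismatch: expected (%d, %d), got (%d, %d)",
                 D, L, nrow(frame), ncol(frame)))
  cs <- colSums(frame != 0)
  if (any(cs > 1)) stop("frame is not one-hot: a column has multiple entries")
  tok <- rep(-1L, L)
  nz <- which(cs == 1)
  if (length(nz)) tok[nz] <- max.col(t(frame[, nz, drop = FALSE]),
                                     ties.method = "first") - 1L
  tok
}

#' Predict class labels for one-hot frames
#'
#' Runs the forward pass and returns the class scores (softmax
#' probabilities, non-negative and summing to 1) together with the argmax
#' labels; ties break toward the lowest class index. Input may be a single
#' \code{D x L} one-hot frame, a \code{D x L x n} array of frames, or an
#' \code{L x n} token matrix from [tokenMatrix()].
#'
#' @param object A trained (or freshly built) [CNNClassifier-class].
#' @param frames Input frame(s) or token matrix (see Details).
#' @param tokens Logical: treat a matrix input as an \code{L x n} token
#'   matrix instead of a single \code{D x L} frame.
#' @param ... Unused.
#' @return List with \code{label} (integer vector, 1..C) and \code{scores}
#'   (\code{n x C} matrix of probabilities). For a single frame,
#'   \code{label} has length 1.
#' @export
setMethod("predict", "CNNClassifier", function(object, frames,
                                               tokens = FALSE, ...) {
  cfg <- object@config
  D <- cfg$dictSize; L <- cfg$frameLength
  tok <- if (is.matrix(frames) && !tokens) {
    matrix(.frameTokens(frames, D, L), ncol = 1)
  } else if (is.matrix(frames)) {
    if (nrow(frames) != L)
      stop(sprintf("token matrix must have L=%d rows, got %d", L, nrow(frames)))
    storage.mode(frames) <- "integer"
    frames
  } else if (is.array(frames) && length(dim(frames)) == 3L) {
    vapply(seq_len(dim(frames)[3]),
           function(i) .frameTokens(frames[, , i], D, L), integer(L))
  } else stop("frames must be a D x L matrix, D x L x n array, or L x n token matrix")
  if (!is.matrix(tok)) tok <- matrix(tok, nrow = L)
  probs <- cnn_predict_cpp(object@params, tok, .cppConfig(cfg))
  list(label = max.col(probs, ties.method = "first"), scores = probs)
})

#' Save / load a model checkpoint
#'
#' The checkpoint is a serialized container holding the format version, the
#' configuration, all parameter arrays and the initialization seed. Loading
#' refuses containers with an unknown version string.
#'
#' @param model A [CNNClassifier-class].
#' @param path Checkpoint file path.
#' @return \code{loadModel}: the restored model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CNNClassifier"))
  saveRDS(list(version = model@version, config = model@config,
               params = model@params, seed = model@seed), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, .MODEL_VERSION))
    stop("unsupported model checkpoint version: ", x$version)
  new("CNNClassifier", config = x$config, params = x$params,
      seed = x$seed, version = x$version)
}
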