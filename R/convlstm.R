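#' Conv-LSTM configuration
#'
#' Defaults follow the deep convolutional LSTM lineage for wearable-sensor
#' activity recognition: stacked 1-D convolutions (kernel 5, ReLU) feeding
#' stacked LSTM layers, finished with a dense softmax over the states. The
#' channel count is read from the data, never hard-coded; the dense output
#' width must equal the dataset vocabulary size. With long (500-sample)
#' inputs a stride-2 max-pool after each convolution keeps the recurrent pass
#' tractable.
#'
#' @param convWidth Convolution filter count (64 by default; 1024 is the
#'   higher-capacity variant).
#' @param kernel Convolution kernel length (default 5).
#' @param nConvLayers Number of stacked convolutions (default 4).
#' @param lstmHidden LSTM hidden size (default 128).
#' @param lstmLayers Number of stacked LSTM layers (default 2).
#' @param denseOut Output classes; `NULL` (default) takes the vocabulary
#'   size of the training data.
#' @param learningRate Adam learning rate (default 1e-3) — the most
#'   influential hyperparameter for this family of models, together with the
#'   hidden size.
#' @param epochs Training epochs (default 300).
#' @param batchSize Mini-batch size (default 64).
#' @param seed RNG seed controlling initialisation, shuffling and the
#'   validation carve-out.
#' @param pool Apply stride-2 max-pooling after each convolution; `NULL`
#'   (default) enables it automatically for inputs of 100+ time steps.
#' @param valFraction Fraction of the training set held out for validation
#'   (default 0.1, stratified).
#' @param patience Early-stopping patience on validation loss (default 25
#'   epochs); `Inf` disables early stopping.
#' @return A classed list of settings.
#' @export
convLSTMConfig <- function(convWidth = 64, kernel = 5, nConvLayers = 4,
                           lstmHidden = 128, lstmLayers = 2, denseOut = NULL,
                           learningRate = 1e-3, epochs = 300, batchSize = 64,
                           seed = 1, pool = NULL, valFraction = 0.1,
                           patience = 25) {
  cfg <- list(convWidth = as.integer(convWidth), kernel = as.integer(kernel),
              nConvLayers = as.integer(nConvLayers),
              lstmHidden = as.integer(lstmHidden),
              lstmLayers = as.integer(lstmLayers),
              denseOut = if (is.null(denseOut)) NULL else as.integer(denseOut),
              learningRate = learningRate, epochs = as.integer(epochs),
              batchSize = as.integer(batchSize), seed = seed, pool = pool,
              valFraction = valFraction, patience = patience)
  stopIfNot(cfg$convWidth >= 1 && cfg$kernel >= 1 && cfg$nConvLayers >= 0 &&
              cfg$lstmHidden >= 1 && cfg$lstmLayers >= 1 &&
              cfg$epochs >= 0 && cfg$batchSize >= 1,
            "invalid Conv-LSTM configuration")
  class(cfg) <- c("ConvLSTMConfig", "list")
  cfg
}

#' ConvLSTMModel: trained convolutional LSTM classifier
#'
#' @slot params Named list of weight matrices/vectors.
#' @slot config The [convLSTMConfig()] the model was trained with.
#' @slot vocabulary Label vocabulary (softmax column order).
#' @slot inputShape `c(T, C)` expected sample shape.
#' @export
setClass("ConvLSTMModel", representation(
  params = "list", config = "list", vocabulary = "character",
  inputShape = "numeric"))

setMethod("show", "ConvLSTMModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("ConvLSTMModel: %d conv x %d (k=%d) -> %d LSTM x %d -> ",
                     "%d classes; input %d x %d\n"),
              cfg$nConvLayers, cfg$convWidth, cfg$kernel, cfg$lstmLayers,
              cfg$lstmHidden, length(object@vocabulary),
              object@inputShape[1], object@inputShape[2]))
})

initConvLSTMParams <- function(cfg, C, K) {
  p <- list()
  cin <- C
  for (l in seq_len(cfg$nConvLayers)) {
    p[[paste0("conv", l, ".W")]] <- glorot(cfg$kernel * cin, cfg$convWidth)
    p[[paste0("conv", l, ".b")]] <- numeric(cfg$convWidth)
    cin <- cfg$convWidth
  }
  din <- cin
  for (l in seq_len(cfg$lstmLayers)) {
    H <- cfg$lstmHidden
    p[[paste0("lstm", l, ".W")]] <- glorot(din + H, 4L * H)
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1          # forget-gate bias
    p[[paste0("lstm", l, ".b")]] <- b
    din <- H
  }
  p[["dense.W"]] <- glorot(din, K)
  p[["dense.b"]] <- numeric(K)
  p
}

convLSTMForward <- function(params, cfg, X, usePool) {
  caches <- list()
  cur <- X
  for (l in seq_len(cfg$nConvLayers)) {
    cv <- convForward(cur, params[[paste0("conv", l, ".W")]],
                      params[[paste0("conv", l, ".b")]])
    rl <- reluForward(cv$out)
    cur <- rl$out
    pl <- NULL
    if (usePool && dim(cur)[2] >= 2L) {
      pl <- poolForward(cur)
      cur <- pl$out
    }
    if (dim(cur)[2] < 1L)
      stop("input too short for the configured convolution stack", call. = FALSE)
    caches[[paste0("conv", l)]] <- list(conv = cv$cache, relu = rl$mask,
                                        pool = pl$cache)
  }
  for (l in seq_len(cfg$lstmLayers)) {
    ls <- lstmForward(cur, params[[paste0("lstm", l, ".W")]],
                      params[[paste0("lstm", l, ".b")]])
    cur <- ls$out
    caches[[paste0("lstm", l)]] <- ls$cache
  }
  TT <- dim(cur)[2]
  hLast <- matrix(cur[, TT, ], dim(cur)[1], dim(cur)[3])
  logits <- sweep(hLast %*% params[["dense.W"]], 2, params[["dense.b"]], "+")
  list(logits = logits, hLast = hLast, caches = caches, seqLen = TT)
}

convLSTMBackward <- function(params, cfg, fw, dLogits, usePool) {
  g <- list()
  g[["dense.W"]] <- crossprod(fw$hLast, dLogits)
  g[["dense.b"]] <- colSums(dLogits)
  dH <- tcrossprod(dLogits, params[["dense.W"]])
  n <- nrow(dH)
  for (l in rev(seq_len(cfg$lstmLayers))) {
    cache <- fw$caches[[paste0("lstm", l)]]
    TT <- length(cache$steps)
    dHseq <- array(0, c(n, TT, cfg$lstmHidden))
    if (l == cfg$lstmLayers) dHseq[, TT, ] <- dH else dHseq <- dH
    bk <- lstmBackward(dHseq, cache)
    g[[paste0("lstm", l, ".W")]] <- bk$dW
    g[[paste0("lstm", l, ".b")]] <- bk$db
    dH <- bk$dX
  }
  dCur <- dH
  for (l in rev(seq_len(cfg$nConvLayers))) {
    cache <- fw$caches[[paste0("conv", l)]]
    if (!is.null(cache$pool)) dCur <- poolBackward(dCur, cache$pool)
    dCur <- reluBackward(dCur, cache$relu)
    dMat <- matrix(dCur, prod(dim(dCur)[1:2]), dim(dCur)[3])
    dW <- crossprod(cache$conv$Xcol, dMat)
    g[[paste0("conv", l, ".W")]] <- dW
    g[[paste0("conv", l, ".b")]] <- colSums(dMat)
    if (l > 1L) dCur <- convBackward(dCur, cache$conv)
  }
  g
}

evalConvLSTM <- function(params, cfg, X, yIdx, usePool, chunk = 512L) {
  n <- dim(X)[1]
  loss <- 0; correct <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    fw <- convLSTMForward(params, cfg, X[idx, , , drop = FALSE], usePool)
    sm <- softmaxCELoss(fw$logits, yIdx[idx])
    loss <- loss + sm$loss * length(idx)
    correct <- correct + sum(max.col(sm$probs, ties.method = "first") == yIdx[idx])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the Conv-LSTM state classifier
#'
#' Mini-batch gradient descent (Adam) on softmax cross-entropy over the
#' training side of a split, with a stratified validation carve-out and
#' optional early stopping on validation loss. Deterministic given the
#' configuration seed.
#'
#' @param split A [SplitVariant-class].
#' @param config A [convLSTMConfig()].
#' @return List with `model` (a [ConvLSTMModel-class]) and `history`
#'   (`data.frame` with per-epoch train/validation loss and accuracy).
#' @export
trainConvLSTM <- function(split, config = convLSTMConfig()) {
  stopIfNot(is(split, "SplitVariant"), "split must be a SplitVariant")
  stopIfNot(inherits(config, "ConvLSTMConfig"),
            "config must come from convLSTMConfig()")
  tr <- trainVariant(split)
  X <- sampleArray(tr)
  vocab <- variantVocabulary(tr)
  K <- length(vocab)
  if (!is.null(config$denseOut) && config$denseOut != K)
    stop(sprintf("configuration error: denseOut = %d but vocabulary has %d labels",
                 config$denseOut, K), call. = FALSE)
  config$denseOut <- K
  d <- dim(X)
  stopIfNot(length(d) == 3L, "samples must share a common (T x C) shape")
  usePool <- if (is.null(config$pool)) d[2] >= 100L else isTRUE(config$pool)
  yIdx <- match(sampleLabels(tr), vocab)

  withSeed(config$seed, {
    params <- initConvLSTMParams(config, d[3], K)
    valIdx <- if (config$valFraction > 0 && d[1] >= 2 * K)
      stratifiedIndices(yIdx, config$valFraction) else integer()
    trIdx <- setdiff(seq_len(d[1]), valIdx)
    opt <- adamInit(params)
    hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                       trainAcc = numeric(), valLoss = numeric(),
                       valAcc = numeric())
    best <- list(loss = Inf, params = params, since = 0L)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(trIdx)
      epLoss <- 0; epCorrect <- 0
      for (s in seq(1L, length(ord), by = config$batchSize)) {
        bi <- ord[s:min(length(ord), s + config$batchSize - 1L)]
        fw <- convLSTMForward(params, config, X[bi, , , drop = FALSE], usePool)
        sm <- softmaxCELoss(fw$logits, yIdx[bi])
        if (!is.finite(sm$loss))
          stop(sprintf("NaN/Inf loss at epoch %d (batch starting %d); ",
                       ep, s), "lower the learning rate", call. = FALSE)
        grads <- convLSTMBackward(params, config, fw, sm$dLogits, usePool)
        upd <- adamStep(params, grads, opt, config$learningRate)
        params <- upd$params; opt <- upd$state
        epLoss <- epLoss + sm$loss * length(bi)
        epCorrect <- epCorrect +
          sum(max.col(sm$probs, ties.method = "first") == yIdx[bi])
      }
      val <- if (length(valIdx))
        evalConvLSTM(params, config, X[valIdx, , , drop = FALSE],
                     yIdx[valIdx], usePool)
      else c(loss = NA_real_, acc = NA_real_)
      hist <- rbind(hist, data.frame(
        epoch = ep, trainLoss = epLoss / length(ord),
        trainAcc = epCorrect / length(ord),
        valLoss = val[["loss"]], valAcc = val[["acc"]]))
      if (length(valIdx) && is.finite(config$patience)) {
        if (val[["loss"]] < best$loss - 1e-9) {
          best <- list(loss = val[["loss"]], params = params, since = 0L)
        } else {
          best$since <- best$since + 1L
          if (best$since >= config$patience) { params <- best$params; break }
        }
      }
    }
    model <- new("ConvLSTMModel", params = params, config = unclass(config),
                 vocabulary = vocab, inputShape = c(d[2], d[3]))
    list(model = model, history = hist)
  })
}

#' Predict states with a trained Conv-LSTM
#'
#' @param model A [ConvLSTMModel-class].
#' @param samples A [SensorVariant-class] or an `n x T x C` array matching
#'   the training shape.
#' @return Character vector of predicted labels; the per-sample class
#'   probability matrix (rows sum to 1) is attached as attribute `"scores"`.
#' @export
predictConvLSTM <- function(model, samples) {
  X <- if (is(samples, "SensorVariant")) sampleArray(samples) else samples
  d <- dim(X)
  stopIfNot(length(d) == 3L && all(d[2:3] == model@inputShape),
            sprintf("sample shape (%s) does not match training shape (%s)",
                    paste(dim(X)[-1], collapse = " x "),
                    paste(model@inputShape, collapse = " x ")))
  cfg <- model@config
  usePool <- if (is.null(cfg$pool)) d[2] >= 100L else isTRUE(cfg$pool)
  probs <- NULL
  for (s in seq(1L, d[1], by = 512L)) {
    idx <- s:min(d[1], s + 511L)
    fw <- convLSTMForward(model@params, cfg, X[idx, , , drop = FALSE], usePool)
    probs <- rbind(probs, softmaxProbs(fw$logits))
  }
  out <- model@vocabulary[max.col(probs, ties.method = "first")]
  colnames(probs) <- model@vocabulary
  attr(out, "scores") <- probs
  out
}
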