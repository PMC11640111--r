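#' Convolutional autoencoder configuration
#'
#' The encoder is a stack of two same-padded 1-D convolutions (ReLU) followed
#' by a dense bottleneck to the latent space; the decoder mirrors it (dense
#' expansion, two convolutions, linear output). The latent dimension defaults
#' to 8 for 25-sample windows and is typically set to 4 when training on full
#' 500-sample interpolated sequences.
#'
#' @param windowLen Input window length `M` (rows of one sample); `NULL`
#'   takes it from the training data.
#' @param latentN Latent dimension `N` (default 8); must be far smaller than
#'   the flattened input size.
#' @param convWidths Filter counts of the two convolution layers (default
#'   `c(16, 8)`).
#' @param kernel Convolution kernel length (default 5, odd).
#' @param overlap Window overlap fraction in `[0, 0.95]` used by
#'   [slidingWindows()] when cutting heavily overlapping training windows
#'   from longer sequences (default 0.75).
#' @param epochs,learningRate,batchSize,seed Training settings.
#' @return A classed list of settings.
#' @export
aeConfig <- function(windowLen = NULL, latentN = 8, convWidths = c(16, 8),
                     kernel = 5, overlap = 0.75, epochs = 200,
                     learningRate = 1e-3, batchSize = 64, seed = 1) {
  stopIfNot(overlap >= 0 && overlap <= 0.95, "overlap must lie in [0, 0.95]")
  stopIfNot(kernel %% 2 == 1, "kernel must be odd (same padding)")
  cfg <- list(windowLen = windowLen, latentN = as.integer(latentN),
              convWidths = as.integer(convWidths), kernel = as.integer(kernel),
              overlap = overlap, epochs = as.integer(epochs),
              learningRate = learningRate, batchSize = as.integer(batchSize),
              seed = seed)
  class(cfg) <- c("AEConfig", "list")
  cfg
}

#' ConvAutoencoder: trained convolutional autoencoder
#'
#' @slot params Named list of weights.
#' @slot config The [aeConfig()] used.
#' @slot inputShape `c(M, C)`.
#' @export
setClass("ConvAutoencoder", representation(
  params = "list", config = "list", inputShape = "numeric"))

setMethod("show", "ConvAutoencoder", function(object) {
  cat(sprintf("ConvAutoencoder: input %d x %d -> latent %d (conv %s)\n",
              object@inputShape[1], object@inputShape[2],
              object@config$latentN,
              paste(object@config$convWidths, collapse = "/")))
})

initAEParams <- function(cfg, M, C) {
  F1 <- cfg$convWidths[1]; F2 <- cfg$convWidths[2]; k <- cfg$kernel
  N <- cfg$latentN
  list(
    "enc1.W" = glorot(k * C, F1), "enc1.b" = numeric(F1),
    "enc2.W" = glorot(k * F1, F2), "enc2.b" = numeric(F2),
    "encD.W" = glorot(M * F2, N), "encD.b" = numeric(N),
    "decD.W" = glorot(N, M * F2), "decD.b" = numeric(M * F2),
    "dec1.W" = glorot(k * F2, F1), "dec1.b" = numeric(F1),
    "dec2.W" = glorot(k * F1, C), "dec2.b" = numeric(C))
}

aeEncodeForward <- function(params, cfg, X) {
  pad <- (cfg$kernel - 1L) %/% 2L
  c1 <- convForward(X, params[["enc1.W"]], params[["enc1.b"]], pad)
  r1 <- reluForward(c1$out)
  c2 <- convForward(r1$out, params[["enc2.W"]], params[["enc2.b"]], pad)
  r2 <- reluForward(c2$out)
  d <- dim(r2$out)
  flat <- matrix(r2$out, d[1], d[2] * d[3])
  z <- sweep(flat %*% params[["encD.W"]], 2, params[["encD.b"]], "+")
  list(z = z, cache = list(c1 = c1$cache, r1 = r1$mask, c2 = c2$cache,
                           r2 = r2$mask, flat = flat, dimR2 = d))
}

aeDecodeForward <- function(params, cfg, z, M, C) {
  pad <- (cfg$kernel - 1L) %/% 2L
  F1 <- cfg$convWidths[1]; F2 <- cfg$convWidths[2]
  n <- nrow(z)
  u <- sweep(z %*% params[["decD.W"]], 2, params[["decD.b"]], "+")
  ru <- reluForward(u)
  cube <- array(ru$out, c(n, M, F2))
  c1 <- convForward(cube, params[["dec1.W"]], params[["dec1.b"]], pad)
  r1 <- reluForward(c1$out)
  c2 <- convForward(r1$out, params[["dec2.W"]], params[["dec2.b"]], pad)
  list(xhat = c2$out,
       cache = list(ru = ru$mask, c1 = c1$cache, r1 = r1$mask, c2 = c2$cache,
                    z = z, u = ru$out, M = M, F2 = F2, n = n))
}

aeBackward <- function(params, cfg, enc, dec, dXhat) {
  g <- list()
  # decoder
  dMat <- matrix(dXhat, prod(dim(dXhat)[1:2]), dim(dXhat)[3])
  g[["dec2.W"]] <- crossprod(dec$cache$c2$Xcol, dMat)
  g[["dec2.b"]] <- colSums(dMat)
  dCur <- convBackward(dXhat, dec$cache$c2)
  dCur <- reluBackward(dCur, dec$cache$r1)
  dMat <- matrix(dCur, prod(dim(dCur)[1:2]), dim(dCur)[3])
  g[["dec1.W"]] <- crossprod(dec$cache$c1$Xcol, dMat)
  g[["dec1.b"]] <- colSums(dMat)
  dCube <- convBackward(dCur, dec$cache$c1)
  dU <- matrix(dCube, dec$cache$n, dec$cache$M * dec$cache$F2)
  dU <- reluBackward(dU, dec$cache$ru)
  g[["decD.W"]] <- crossprod(dec$cache$z, dU)
  g[["decD.b"]] <- colSums(dU)
  dZ <- tcrossprod(dU, params[["decD.W"]])
  # encoder
  g[["encD.W"]] <- crossprod(enc$cache$flat, dZ)
  g[["encD.b"]] <- colSums(dZ)
  dFlat <- tcrossprod(dZ, params[["encD.W"]])
  dR2 <- array(dFlat, enc$cache$dimR2)
  dR2 <- reluBackward(dR2, enc$cache$r2)
  dMat <- matrix(dR2, prod(dim(dR2)[1:2]), dim(dR2)[3])
  g[["enc2.W"]] <- crossprod(enc$cache$c2$Xcol, dMat)
  g[["enc2.b"]] <- colSums(dMat)
  dR1 <- convBackward(dR2, enc$cache$c2)
  dR1 <- reluBackward(dR1, enc$cache$r1)
  dMat <- matrix(dR1, prod(dim(dR1)[1:2]), dim(dR1)[3])
  g[["enc1.W"]] <- crossprod(enc$cache$c1$Xcol, dMat)
  g[["enc1.b"]] <- colSums(dMat)
  g
}

#' Train the convolutional autoencoder
#'
#' Minimises mean squared reconstruction error with Adam; deterministic given
#' the configuration seed.
#'
#' @param samples `n x M x C` array (or a [SensorVariant-class]) of training
#'   windows sharing one shape.
#' @param config An [aeConfig()].
#' @return List with `ae` (a [ConvAutoencoder-class]) and `history`
#'   (`data.frame` of per-epoch mean squared error).
#' @export
trainAutoencoder <- function(samples, config = aeConfig()) {
  X <- if (is(samples, "SensorVariant")) sampleArray(samples) else samples
  d <- dim(X)
  stopIfNot(length(d) == 3L, "samples must form an n x M x C array")
  stopIfNot(inherits(config, "AEConfig"), "config must come from aeConfig()")
  if (is.null(config$windowLen)) config$windowLen <- d[2]
  stopIfNot(config$windowLen == d[2],
            "configured windowLen does not match the data")
  M <- d[2]; C <- d[3]
  if (config$latentN >= M * C)
    stop(sprintf("configuration error: latent dimension %d must be smaller than %d",
                 config$latentN, M * C), call. = FALSE)
  withSeed(config$seed, {
    params <- initAEParams(config, M, C)
    opt <- adamInit(params)
    hist <- data.frame(epoch = integer(), mse = numeric())
    n <- d[1]
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      epLoss <- 0
      for (s in seq(1L, n, by = config$batchSize)) {
        bi <- ord[s:min(n, s + config$batchSize - 1L)]
        Xb <- X[bi, , , drop = FALSE]
        enc <- aeEncodeForward(params, config, Xb)
        dec <- aeDecodeForward(params, config, enc$z, M, C)
        resid <- dec$xhat - Xb
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("NaN/Inf loss at epoch ", ep, "; lower the learning rate",
               call. = FALSE)
        grads <- aeBackward(params, config, enc, dec,
                            2 * resid / length(resid))
        upd <- adamStep(params, grads, opt, config$learningRate)
        params <- upd$params; opt <- upd$state
        epLoss <- epLoss + loss * length(bi)
      }
      hist <- rbind(hist, data.frame(epoch = ep, mse = epLoss / n))
    }
    list(ae = new("ConvAutoencoder", params = params,
                  config = unclass(config), inputShape = c(M, C)),
         history = hist)
  })
}

#' Encode samples into the latent space
#'
#' @param ae A [ConvAutoencoder-class].
#' @param samples `n x M x C` array or [SensorVariant-class] matching the
#'   training shape.
#' @return `n x N` matrix of latent points.
#' @export
encodeSamples <- function(ae, samples) {
  X <- if (is(samples, "SensorVariant")) sampleArray(samples) else samples
  d <- dim(X)
  stopIfNot(length(d) == 3L && all(d[2:3] == ae@inputShape),
            "sample shape does not match the autoencoder input shape")
  aeEncodeForward(ae@params, ae@config, X)$z
}

#' Decode latent points back to sequences
#'
#' The decoder acts as the functional inverse from the latent space back to
#' the input space, which is what makes it a natural pre-image map.
#'
#' @param ae A [ConvAutoencoder-class].
#' @param phi Latent vector of length `N`, or an `n x N` matrix.
#' @return `M x C` matrix for a single vector, else an `n x M x C` array.
#' @export
decodeLatent <- function(ae, phi) {
  single <- is.null(dim(phi))
  Z <- if (single) matrix(phi, 1) else as.matrix(phi)
  stopIfNot(ncol(Z) == ae@config$latentN,
            sprintf("latent length must be %d", ae@config$latentN))
  out <- aeDecodeForward(ae@params, ae@config, Z,
                         ae@inputShape[1], ae@inputShape[2])$xhat
  if (single) matrix(out[1, , ], ae@inputShape[1], ae@inputShape[2]) else out
}

#' Cut heavily overlapping windows from a sequence
#'
#' @param mat `T x C` matrix (e.g. an aligned 500-sample event).
#' @param width Window length.
#' @param overlap Overlap fraction in `[0, 0.95]`; the hop is
#'   `max(1, round(width * (1 - overlap)))` rows.
#' @return `n x width x C` array of windows.
#' @export
slidingWindows <- function(mat, width, overlap = 0.75) {
  if (is(mat, "AlignedSequence")) mat <- mat@values
  stopIfNot(is.matrix(mat) && nrow(mat) >= width,
            "mat must be a matrix with at least `width` rows")
  stopIfNot(overlap >= 0 && overlap <= 0.95, "overlap must lie in [0, 0.95]")
  hop <- max(1L, as.integer(round(width * (1 - overlap))))
  starts <- seq(1L, nrow(mat) - width + 1L, by = hop)
  out <- array(0, c(length(starts), width, ncol(mat)))
  for (i in seq_along(starts))
    out[i, , ] <- mat[starts[i]:(starts[i] + width - 1L), ]
  out
}
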