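# Minimal neural-network kernels used by the Conv-LSTM classifier and the
# convolutional autoencoder: 1-D convolutions via im2col, LSTM with full
# backpropagation through time, dense layers, softmax cross-entropy, MSE and
# Adam. Arrays are (n, T, C): sample x time x channel, matricised column-major
# so row r of a flattened (n*T, C) matrix is (sample i, time t) with i fastest.

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -l, l), nin, nout)
}

sigm <- function(x) 1 / (1 + exp(-x))

im2col <- function(X, k) {
  d <- dim(X); n <- d[1]; TT <- d[2]; C <- d[3]
  To <- TT - k + 1L
  out <- matrix(0, n * To, k * C)
  for (j in seq_len(k))
    out[, ((j - 1L) * C + 1L):(j * C)] <-
      matrix(X[, j:(To + j - 1L), , drop = FALSE], n * To, C)
  out
}

convForward <- function(X, W, b, pad = 0L) {
  if (pad > 0L) {
    d <- dim(X)
    Xp <- array(0, c(d[1], d[2] + 2L * pad, d[3]))
    Xp[, (pad + 1L):(pad + d[2]), ] <- X
    X <- Xp
  }
  d <- dim(X)
  k <- nrow(W) / d[3]
  To <- d[2] - k + 1L
  Xcol <- im2col(X, k)
  outMat <- sweep(Xcol %*% W, 2, b, "+")
  list(out = array(outMat, c(d[1], To, ncol(W))),
       cache = list(Xcol = Xcol, dimX = d, k = k, W = W, pad = pad))
}

convBackward <- function(dOut, cache) {
  d <- cache$dimX; k <- cache$k; W <- cache$W
  n <- d[1]; C <- d[3]; To <- dim(dOut)[2]
  dMat <- matrix(dOut, n * To, dim(dOut)[3])
  dW <- crossprod(cache$Xcol, dMat)
  db <- colSums(dMat)
  dXcol <- tcrossprod(dMat, W)
  dX <- array(0, d)
  for (j in seq_len(k))
    dX[, j:(To + j - 1L), ] <- dX[, j:(To + j - 1L), ] +
      array(dXcol[, ((j - 1L) * C + 1L):(j * C)], c(n, To, C))
  if (cache$pad > 0L)
    dX <- dX[, (cache$pad + 1L):(d[2] - cache$pad), , drop = FALSE]
  dX
}

reluForward <- function(X) list(out = pmax(X, 0), mask = X > 0)
reluBackward <- function(dOut, mask) dOut * mask

poolForward <- function(X) {
  d <- dim(X); To <- d[2] %/% 2L
  i1 <- seq(1L, 2L * To, 2L); i2 <- i1 + 1L
  A <- X[, i1, , drop = FALSE]; B <- X[, i2, , drop = FALSE]
  mask <- A >= B
  list(out = pmax(A, B), cache = list(mask = mask, dimX = d, i1 = i1, i2 = i2))
}

poolBackward <- function(dOut, cache) {
  dX <- array(0, cache$dimX)
  dX[, cache$i1, ] <- dOut * cache$mask
  dX[, cache$i2, ] <- dOut * !cache$mask
  dX
}

lstmForward <- function(X, W, b) {
  d <- dim(X); n <- d[1]; TT <- d[2]; D <- d[3]
  H <- length(b) %/% 4L
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  Hseq <- array(0, c(n, TT, H))
  steps <- vector("list", TT)
  for (t in seq_len(TT)) {
    z <- cbind(matrix(X[, t, ], n, D), h)
    a <- sweep(z %*% W, 2, b, "+")
    i <- sigm(a[, 1:H, drop = FALSE])
    f <- sigm(a[, (H + 1):(2 * H), drop = FALSE])
    o <- sigm(a[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(a[, (3 * H + 1):(4 * H), drop = FALSE])
    cNew <- f * cc + i * g
    tc <- tanh(cNew)
    hNew <- o * tc
    steps[[t]] <- list(z = z, i = i, f = f, o = o, g = g, cPrev = cc, tc = tc)
    h <- hNew; cc <- cNew
    Hseq[, t, ] <- hNew
  }
  list(out = Hseq, cache = list(steps = steps, W = W, D = D, H = H, n = n))
}

# dHseq: gradient wrt the full hidden sequence (n, T, H); zero-filled slices
# are fine when only the last step receives gradient.
lstmBackward <- function(dHseq, cache) {
  W <- cache$W; D <- cache$D; H <- cache$H; n <- cache$n
  TT <- dim(dHseq)[2]
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(4L * H)
  dX <- array(0, c(n, TT, D))
  dh <- matrix(0, n, H); dc <- matrix(0, n, H)
  for (t in rev(seq_len(TT))) {
    st <- cache$steps[[t]]
    dh <- dh + matrix(dHseq[, t, ], n, H)
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$cPrev
    dcPrev <- dc * st$f
    da <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o), dg * (1 - st$g^2))
    dW <- dW + crossprod(st$z, da)
    db <- db + colSums(da)
    dz <- tcrossprod(da, W)
    dX[, t, ] <- dz[, seq_len(D), drop = FALSE]
    dh <- dz[, (D + 1L):(D + H), drop = FALSE]
    dc <- dcPrev
  }
  list(dX = dX, dW = dW, db = db)
}

softmaxProbs <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# yIdx: integer class per row. Returns mean cross-entropy and dLogits.
softmaxCELoss <- function(logits, yIdx) {
  p <- softmaxProbs(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yIdx)], 1e-12)))
  dL <- p
  dL[cbind(seq_len(n), yIdx)] <- dL[cbind(seq_len(n), yIdx)] - 1
  list(loss = loss, dLogits = dL / n, probs = p)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# stratified index split used for validation carving and related helpers
stratifiedIndices <- function(labels, fraction) {
  sel <- integer()
  for (cl in sort(unique(as.character(labels)))) {
    i <- which(labels == cl)
    k <- max(1L, round(fraction * length(i)))
    if (length(i) > 1L) sel <- c(sel, sample(i, min(k, length(i) - 1L)))
  }
  sort(sel)
}
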