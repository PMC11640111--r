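# Exact t-distributed stochastic neighbour embedding, used to visualise the
# autoencoder latent space in 2-D. O(n^2) per iteration, which is ample for
# the latent sets the lexicon pipeline produces.

# Conditional Gaussian affinities at a fixed perplexity via binary search on
# the per-point precision beta.
tsnePerplexity <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP < .Machine$double.xmin) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else { betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P
}

#' 2-D t-SNE embedding of latent points
#'
#' Classic exact t-SNE: symmetrised Gaussian input affinities at the given
#' perplexity, Student-t low-dimensional kernel, gradient descent with early
#' exaggeration, momentum and adaptive gains. Reproducible given the seed.
#'
#' @param latents `n x N` matrix of latent points (`n >= 10`).
#' @param perplexity Effective neighbour count (default 30); requires
#'   `n - 1 >= 3 * perplexity`.
#' @param seed RNG seed for the random initialisation.
#' @param maxIter Gradient-descent iterations (default 500).
#' @return `n x 2` matrix of embedding coordinates.
#' @export
embedLatents <- function(latents, perplexity = 30, seed = 1, maxIter = 500) {
  X <- as.matrix(latents)
  n <- nrow(X)
  stopIfNot(n >= 10L, "need at least 10 latent points")
  if (n - 1 < 3 * perplexity)
    stop(sprintf("perplexity %g too large for %d points (need n-1 >= 3*perplexity)",
                 perplexity, n), call. = FALSE)
  stopIfNot(all(is.finite(X)), "latents must be finite")
  D2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  D2 <- pmax(D2, 0); diag(D2) <- 0
  P <- tsnePerplexity(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    momentum <- 0.5; eta <- 100
    Pex <- P * 4                       # early exaggeration
    for (iter in seq_len(maxIter)) {
      Pit <- if (iter <= 100) Pex else P
      if (iter == 101) momentum <- 0.8
      num <- 1 / (1 + outer(rowSums(Y^2), rowSums(Y^2), "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- pmax(0.01, ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8))
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
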