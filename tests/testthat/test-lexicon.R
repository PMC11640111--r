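aeTestFit <- function(nPer = 50, epochs = 120, seed = 31, noise = 0.03) {
  mw <- motifWindows(nPer = nPer, noise = noise, seed = seed)
  fit <- trainAutoencoder(mw$X, aeConfig(latentN = 8, epochs = epochs,
                                         batchSize = 32, seed = seed))
  list(mw = mw, fit = fit)
}

test_that("the autoencoder compresses planted motifs well below the variance baseline", {
  r <- aeTestFit()
  X <- r$mw$X
  dataVar <- mean((X - mean(X))^2)     # MSE of the constant-mean predictor
  finalMSE <- tail(r$fit$history$mse, 1)
  expect_lt(finalMSE, 0.1 * dataVar)
  # same seed -> identical final loss
  fit2 <- trainAutoencoder(X, aeConfig(latentN = 8, epochs = 120,
                                       batchSize = 32, seed = 31))
  expect_identical(tail(fit2$history$mse, 1), finalMSE)
  # latent must be genuinely compressive
  expect_lt(r$fit$ae@config$latentN, prod(r$fit$ae@inputShape))
  expect_error(trainAutoencoder(X, aeConfig(latentN = 75, epochs = 1)),
               "configuration error")
})

test_that("encode/decode have the documented shapes and round-trip contract", {
  r <- aeTestFit(nPer = 40, epochs = 100, seed = 32)
  X <- r$mw$X
  Z <- encodeSamples(r$fit$ae, X)
  expect_equal(dim(Z), c(dim(X)[1], 8))
  expect_true(all(is.finite(Z)))
  # identical inputs -> identical latents (batch-size floating-point jitter only)
  expect_equal(Z[1, ], as.numeric(encodeSamples(
    r$fit$ae, X[1, , , drop = FALSE])), tolerance = 1e-10)
  # decode(encode(x)) stays within twice the final training error
  Xhat <- decodeLatent(r$fit$ae, Z)
  mse <- mean((Xhat - X)^2)
  expect_lte(mse, 2 * tail(r$fit$history$mse, 1) + 1e-8)
  # single-vector decode gives an M x C matrix; continuity in phi
  d0 <- decodeLatent(r$fit$ae, Z[1, ])
  expect_equal(dim(d0), c(25L, 3L))
  d1 <- decodeLatent(r$fit$ae, Z[1, ] + 1e-6)
  expect_lt(max(abs(d1 - d0)), 1e-3)
  expect_error(decodeLatent(r$fit$ae, numeric(3)), "latent length")
})

test_that("the 2-D embedding is reproducible and keeps duplicates together", {
  withr::with_seed(33, {
    Z <- rbind(matrix(rnorm(60 * 4, 0), 60, 4),
               matrix(rnorm(60 * 4, 6), 60, 4))
    Z <- rbind(Z, Z[1, ], Z[1, ])      # two exact duplicates of point 1
    Y <- embedLatents(Z, perplexity = 15, seed = 2, maxIter = 350)
    expect_equal(ncol(Y), 2)
    expect_identical(Y, embedLatents(Z, perplexity = 15, seed = 2,
                                     maxIter = 350))
    dAll <- as.matrix(dist(Y))
    dupDist <- max(dAll[121, 122], dAll[121, 1])
    expect_lte(dupDist, quantile(dAll[upper.tri(dAll)], 0.01))
    expect_error(embedLatents(Z[1:20, ], perplexity = 30), "perplexity")
    expect_error(embedLatents(Z[1:5, ], perplexity = 2), "at least 10")
  })
})

test_that("the lexicon recovers planted motifs as distinct pre-images", {
  r <- aeTestFit(nPer = 60, epochs = 150, seed = 34)
  Z <- encodeSamples(r$fit$ae, r$mw$X)
  Y <- embedLatents(Z, perplexity = 20, seed = 3, maxIter = 400)
  lex <- buildLexicon(r$fit$ae, Z, Y, nPeaks = 3)
  entries <- lexiconEntries(lex)
  expect_lte(length(entries), 3)
  expect_equal(length(entries), 3)
  # densities sorted descending, members present, pre-images well-shaped
  dens <- vapply(entries, function(e) e$density, numeric(1))
  expect_true(all(diff(dens) <= 0))
  expect_true(all(vapply(entries, function(e) e$memberCount, numeric(1)) > 0))
  # nearest-MSE assignment maps the three pre-images to three distinct motifs
  assign <- vapply(entries, function(e) {
    which.min(vapply(r$mw$motifs, function(m) mean((m - e$preImage)^2),
                     numeric(1)))
  }, integer(1))
  expect_setequal(assign, 1:3)
})

test_that("degenerate latent clouds collapse to a single lexicon entry", {
  r <- aeTestFit(nPer = 20, epochs = 30, seed = 35)
  Z <- matrix(rep(c(1, 2, 3, 4, 0, 0, 0, 0), each = 25), 25, 8)
  Y <- matrix(0, 25, 2)
  lex <- buildLexicon(r$fit$ae, Z, Y, nPeaks = 3)
  expect_length(lexiconEntries(lex), 1)
  e <- lexiconEntries(lex)[[1]]
  expect_equal(e$memberCount, 25)
  expect_equal(e$preImage, decodeLatent(r$fit$ae, Z[1, ]), tolerance = 1e-12)
})

test_that("double integration matches closed forms and is linear", {
  # zero in, zero out
  expect_equal(doubleIntegrate(numeric(100), dt = 0.01), numeric(100))
  # constant acceleration: p(T) = a T^2 / 2
  n <- 1001; dt <- 2 / (n - 1)
  p <- doubleIntegrate(rep(3, n), dt = dt)
  expect_equal(tail(p, 1), 3 * 2^2 / 2, tolerance = 1e-6)
  # sinusoid: a = sin(wt) -> p = t/w - sin(wt)/w^2
  w <- 2 * pi
  tt <- dt * (0:(n - 1))
  pSin <- doubleIntegrate(sin(w * tt), dt = dt)
  expect_equal(pSin, tt / w - sin(w * tt) / w^2, tolerance = 1e-4)
  # linearity to machine precision
  withr::with_seed(36, {
    a <- rnorm(200); b <- rnorm(200)
    expect_equal(doubleIntegrate(a + b, 0.01),
                 doubleIntegrate(a, 0.01) + doubleIntegrate(b, 0.01),
                 tolerance = 1e-9)
  })
  expect_error(doubleIntegrate(a, dt = 0), "dt")
  # matrix input keeps its shape
  expect_equal(dim(doubleIntegrate(cbind(a, b), 0.01)), c(200L, 2L))
})

test_that("axis-plane trajectories preserve order and reflect on sign flips", {
  tt <- seq(0, 2 * pi, length.out = 200)
  imu <- cbind(x = sin(tt), y = cos(tt), z = tt)
  tr <- axisPlaneTrajectory(imu, c("x", "y"))
  expect_equal(nrow(tr), 200)
  # pure sine vs cosine: closed ellipse (start == end after a full period)
  expect_lt(sqrt(sum((tr[1, ] - tr[200, ])^2)), 1e-6)
  # flipping axis 2 mirrors across the first axis
  imu2 <- imu; imu2[, "y"] <- -imu2[, "y"]
  tr2 <- axisPlaneTrajectory(imu2, c("x", "y"))
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$y, -tr$y)
  expect_error(axisPlaneTrajectory(imu, c("x", "w")), "unknown axis")
})
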