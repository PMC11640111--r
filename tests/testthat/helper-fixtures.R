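# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# A small catalogue of k well-separated motifs.
tinyCatalogue <- function(k = 3, freqs = c(1, 4, 8), amps = c(1, 1.5, 0.7),
                          noise = 0.05, burst = 0, audioLevel = 0) {
  data.frame(state = paste0("S", seq_len(k)),
             base = seq(0, by = 0.1, length.out = k),
             amplitude = rep_len(amps, k), frequency = rep_len(freqs, k),
             noiseSd = rep_len(noise, k), jerkFactor = rep_len(0.5, k),
             audioBurstProb = rep_len(burst, k),
             audioLevel = rep_len(audioLevel, k),
             envDriftRate = rep_len(0.002, k), stringsAsFactors = FALSE)
}

tinyCohort <- function(nDogs = 2, k = 3, durationRange = c(1.5, 2.5),
                       seed = 1, normalize = TRUE, ...) {
  cfg <- cohortConfig(nDogs = nDogs, catalogue = tinyCatalogue(k, ...),
                      durationRange = durationRange, masterSeed = seed)
  coh <- generateCohort(cfg)
  if (normalize) coh <- lapply(coh, function(s) znormalizeSession(s)$session)
  coh
}

# Build a session by hand with chosen per-modality values (1 Hz streams get
# floor(dur) samples, 100 Hz streams 100*dur).
makeTestSession <- function(dur = 3, temperature = NULL, imu = NULL,
                            events = NULL) {
  nHi <- as.integer(dur * 100); nLo <- as.integer(dur)
  tHi <- (seq_len(nHi) - 1) / 100; tLo <- seq_len(nLo) - 1
  if (is.null(imu)) imu <- matrix(sin(tHi + rep(1:3, each = nHi)), nHi, 3)
  if (is.null(temperature)) temperature <- 20 + 0.01 * tLo
  one <- function(m, tt, v) new("SensorStream", modality = m,
                                rateHz = if (m %in% c("imu", "audio", "light")) 100 else 1,
                                timestamps = tt, values = cbind(v))
  if (is.null(events))
    events <- data.frame(state = "S1", start_s = 0, end_s = dur,
                         stringsAsFactors = FALSE)
  new("CollarSession", dogId = "test", seed = 0,
      streams = list(imu = one("imu", tHi, imu),
                     audio = one("audio", tHi, 40 + cos(tHi)),
                     light = one("light", tHi, 300 + tHi),
                     temperature = one("temperature", tLo, temperature),
                     humidity = one("humidity", tLo, 45 + 0.1 * tLo),
                     pressure = one("pressure", tLo, 1013 - 0.05 * tLo)),
      events = events, durationS = dur, normalized = FALSE)
}

# Windows of k fixed planted motif waveforms (same phase within a motif).
motifWindows <- function(nPer = 50, freqs = c(1, 4, 8), amps = c(1, 1.5, 0.7),
                         phases = c(0, 1, 2), noise = 0.03, M = 25, C = 3,
                         seed = 1) {
  withr::with_seed(seed, {
    k <- length(freqs)
    tt <- (seq_len(M) - 1) / M
    X <- array(0, c(k * nPer, M, C))
    labs <- character(k * nPer)
    for (g in seq_len(k)) for (i in seq_len(nPer)) {
      r <- (g - 1) * nPer + i
      for (a in seq_len(C))
        X[r, , a] <- amps[g] * sin(2 * pi * freqs[g] * tt + phases[g] + a) +
          rnorm(M, 0, noise)
      labs[r] <- paste0("M", g)
    }
    list(X = X, labels = labs,
         motifs = lapply(seq_len(k), function(g) {
           m <- sapply(seq_len(C), function(a)
             amps[g] * sin(2 * pi * freqs[g] * tt + phases[g] + a))
           m
         }))
  })
}

# Wrap an array as a SensorVariant (subsample-shaped windows).
asVariant <- function(X, labels) {
  new("SensorVariant", sampling = "subsample", nStates = length(unique(labels)),
      fusion = "IMU", samples = X, labels = labels,
      vocabulary = sort(unique(labels)),
      provenance = data.frame(dogId = "d", eventIndex = seq_len(dim(X)[1]),
                              windowIndex = NA_integer_))
}

# Independent KPCA oracle: explicit centering matrix H K H and dense eigen.
naiveKpcaProjection <- function(X, gamma, nComponents) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- exp(-gamma * sum((X[i, ] - X[j, ])^2))
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  e <- eigen(Kc, symmetric = TRUE)
  keep <- seq_len(min(nComponents, sum(e$values > 1e-10 * e$values[1])))
  sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(e$values[keep]), "*")
}

# Brute-force macro metrics by explicit per-class loops.
bruteMacro <- function(cm) {
  K <- nrow(cm)
  prec <- rec <- f1 <- numeric(K)
  for (i in 1:K) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(macroPrecision = mean(prec), macroRecall = mean(rec),
       macroF1 = mean(f1), accuracy = sum(diag(cm)) / sum(cm))
}

# Compare matrices column-wise up to sign.
expectEqualUpToSign <- function(A, B, tol = 1e-6) {
  expect_equal(dim(A), dim(B))
  for (j in seq_len(ncol(A))) {
    d <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(d, tol)
  }
}
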