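test_that("Z-normalization uses population statistics per modality", {
  s <- makeTestSession(dur = 3, temperature = c(1, 2, 3))
  z <- znormalizeSession(s)
  expect_equal(as.numeric(sessionStream(z$session, "temperature")@values),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  st <- z$stats
  expect_equal(st$mu[st$modality == "temperature"], 2)
  expect_equal(st$sigma[st$modality == "temperature"], sqrt(2 / 3))
  # every modality standardized: mean 0, population SD 1
  for (m in c("imu", "audio", "light", "humidity", "pressure")) {
    v <- sessionStream(z$session, m)@values
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
})

test_that("Z-normalization handles constant channels and is affine-invariant", {
  s <- makeTestSession(dur = 3, temperature = c(5, 5, 5))
  expect_warning(z <- znormalizeSession(s), "constant")
  expect_equal(as.numeric(sessionStream(z$session, "temperature")@values),
               c(0, 0, 0))

  # Z(aX + b) == Z(X) for a > 0
  s1 <- makeTestSession(dur = 3, temperature = c(1, 4, 6))
  s2 <- makeTestSession(dur = 3, temperature = 2.5 * c(1, 4, 6) + 7)
  z1 <- znormalizeSession(s1); z2 <- znormalizeSession(s2)
  expect_equal(sessionStream(z1$session, "temperature")@values,
               sessionStream(z2$session, "temperature")@values,
               tolerance = 1e-9)

  # idempotence for non-constant modalities
  zz <- znormalizeSession(z1$session)
  expect_equal(sessionStream(zz$session, "imu")@values,
               sessionStream(z1$session, "imu")@values, tolerance = 1e-9)
})

test_that("interpolation is exact on affine signals and spans the event", {
  ev <- data.frame(state = "S1", start_s = 0, end_s = 3.99,
                   stringsAsFactors = FALSE)
  s <- makeTestSession(dur = 4, imu = cbind(2 * (0:399) / 100 + 1,
                                            -0.5 * (0:399) / 100,
                                            rep(3, 400)),
                       temperature = 20 + 0.5 * (0:3), events = ev)
  al <- interpolateEvent(s, 1, "IMU")
  expect_s4_class(al, "AlignedSequence")
  expect_equal(dim(al@values), c(500L, 3L))
  grid <- seq(0, 3.99, length.out = 500)
  expect_equal(unname(al@values[, 1]), 2 * grid + 1, tolerance = 1e-9)
  expect_equal(unname(al@values[, 2]), -0.5 * grid, tolerance = 1e-9)
  expect_equal(unname(al@values[, 3]), rep(3, 500), tolerance = 1e-12)
})

test_that("interpolation matches a brute-force two-point oracle", {
  withr::with_seed(11, {
    s <- makeTestSession(dur = 3)
    al <- interpolateEvent(s, 1, "IMU-Audio-Env")
    expect_equal(ncol(al@values), 8L)
    grid <- seq(0, 3, length.out = 500)
    # brute force: locate bracketing source samples and interpolate by hand
    src <- sessionStream(s, "humidity")
    ora <- vapply(grid, function(g) {
      tt <- src@timestamps; vv <- src@values[, 1]
      if (g <= tt[1]) return(vv[1])
      if (g >= tt[length(tt)]) return(vv[length(vv)])
      i <- max(which(tt <= g))
      vv[i] + (vv[i + 1] - vv[i]) * (g - tt[i]) / (tt[i + 1] - tt[i])
    }, numeric(1))
    expect_equal(al@values[, "humidity"], ora, tolerance = 1e-9,
                 ignore_attr = TRUE)
  })
})

test_that("a single in-event low-rate sample yields a constant channel", {
  s <- makeTestSession(dur = 1.4, temperature = 21.5)
  al <- interpolateEvent(s, 1, "IMU-Audio-Env")
  expect_equal(unique(al@values[, "temperature"]), 21.5, ignore_attr = TRUE)
})

test_that("windowing partitions an aligned event into 20 ordered windows", {
  withr::with_seed(3, {
    mat <- matrix(rnorm(500 * 4), 500, 4)
    w <- windowSequence(mat)
    expect_length(w, 20)
    expect_identical(do.call(rbind, w), mat)
    for (k in c(0, 7, 19))
      expect_identical(w[[k + 1]], mat[(25 * k + 1):(25 * k + 25), ])
    expect_error(windowSequence(mat[1:490, ]), "not divisible")
  })
})

test_that("selectTopStates ranks by recall with lexicographic ties", {
  nm <- paste0("s", sprintf("%02d", 1:12))
  cm <- diag(5, 12); dimnames(cm) <- list(nm, nm)
  expect_identical(selectTopStates(cm, 10), nm[1:10])   # all tied -> lexicographic
  cm2 <- cm
  cm2["s03", "s03"] <- 1; cm2["s03", "s01"] <- 9        # s03 recall 0.1
  top <- selectTopStates(cm2, 11)
  expect_false("s03" %in% top)
  expect_identical(sort(selectTopStates(cm2, 12)), sort(nm))
  expect_error(selectTopStates(cm2, 13), "k must")
})

test_that("dataset variants have the documented shapes and 20x relation", {
  coh <- tinyCohort(nDogs = 2, k = 3)
  vI <- buildDatasetVariant(coh, "interpolate", 3, "IMU")
  vS <- buildDatasetVariant(coh, "subsample", 3, "IMU")
  expect_equal(nSamples(vI), 2 * 3)
  expect_equal(nSamples(vS), 20 * nSamples(vI))
  expect_equal(dim(sampleArray(vI))[2:3], c(500, 3))
  expect_equal(dim(sampleArray(vS))[2:3], c(25, 3))
  vA <- buildDatasetVariant(coh, "interpolate", 3, "IMU-Audio")
  vE <- buildDatasetVariant(coh, "interpolate", 3, "IMU-Audio-Env")
  expect_equal(dim(sampleArray(vA))[3], 4)
  expect_equal(dim(sampleArray(vE))[3], 8)
  # restricting to a subset shrinks the vocabulary accordingly
  v2 <- buildDatasetVariant(coh, "interpolate", 2, "IMU",
                            stateSubset = c("S1", "S3"))
  expect_identical(variantVocabulary(v2), c("S1", "S3"))
  expect_equal(nSamples(v2), 4)
  # windows of one event reproduce the aligned event exactly
  al <- interpolateEvent(coh[[1]], 1, "IMU")
  idx <- which(vS@provenance$dogId == dogId(coh[[1]]) &
                 vS@provenance$eventIndex == 1)
  rebuilt <- do.call(rbind, lapply(idx, function(i)
    matrix(sampleArray(vS)[i, , ], 25, 3)))
  expect_equal(rebuilt, al@values, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("insufficient per-state data raises an explicit error", {
  coh <- tinyCohort(nDogs = 1, k = 2)
  expect_error(buildDatasetVariant(coh, "interpolate", 2, "IMU",
                                   minPerState = 5),
               "insufficient data")
})

test_that("train/test split is stratified, reproducible and leakage-safe", {
  coh <- tinyCohort(nDogs = 5, k = 5)
  v <- buildDatasetVariant(coh, "subsample", 5, "IMU")   # 500 windows
  spW <- splitTrainTest(v, 0.7, seed = 4, level = "window")
  expect_equal(length(spW@trainIdx), 350)
  expect_equal(length(spW@testIdx), 150)
  spW2 <- splitTrainTest(v, 0.7, seed = 4, level = "window")
  expect_identical(spW@trainIdx, spW2@trainIdx)

  spE <- splitTrainTest(v, 0.7, seed = 4, level = "event")
  pv <- v@provenance
  evTrain <- unique(paste(pv$dogId[spE@trainIdx], pv$eventIndex[spE@trainIdx]))
  evTest <- unique(paste(pv$dogId[spE@testIdx], pv$eventIndex[spE@testIdx]))
  expect_length(intersect(evTrain, evTest), 0)
  # stratified: both sides contain every label
  expect_setequal(unique(sampleLabels(trainVariant(spE))), variantVocabulary(v))
  expect_setequal(unique(sampleLabels(testVariant(spE))), variantVocabulary(v))

  # a label with a single group goes to train, with a warning
  coh1 <- tinyCohort(nDogs = 1, k = 2)
  v1 <- buildDatasetVariant(coh1, "interpolate", 2, "IMU")
  w <- capture_warnings(sp1 <- splitTrainTest(v1, 0.7, seed = 1,
                                              level = "event"))
  expect_match(w, "fewer than 2 groups", all = TRUE)
  expect_equal(length(sp1@trainIdx), 2)
})

test_that("pipeline conserves samples: nothing is dropped silently", {
  coh <- tinyCohort(nDogs = 3, k = 4)
  v <- buildDatasetVariant(coh, "subsample", 4, "IMU")
  expect_equal(nSamples(v), 3 * 4 * 20)
  sp <- splitTrainTest(v, 0.7, seed = 2, level = "event")
  expect_equal(length(sp@trainIdx) + length(sp@testIdx), nSamples(v))
})
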