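test_that("a degenerate motif (no oscillation, no noise) produces constant IMU at base", {
  cat1 <- tinyCatalogue(1, freqs = 0, amps = 0, noise = 0)
  cat1$base <- 0.7
  cat1$jerkFactor <- 1.5
  cfg <- cohortConfig(nDogs = 1, catalogue = cat1, durationRange = c(2, 2),
                      noiseScale = 0, masterSeed = 1)
  s <- generateSession(cfg, "d1", 5)
  imu <- sessionStream(s, "imu")@values
  expect_equal(max(abs(imu - 0.7)), 0, tolerance = 1e-12)
})

test_that("sample counts follow the sampling rates: 100 Hz and 1 Hz", {
  cfg <- cohortConfig(nDogs = 1, catalogue = tinyCatalogue(3),
                      durationRange = c(5, 5), masterSeed = 1)
  s <- generateSession(cfg, "d1", 2)
  ev <- sessionEvents(s)
  for (e in seq_len(nrow(ev))) {
    tHi <- sessionStream(s, "imu")@timestamps
    tLo <- sessionStream(s, "temperature")@timestamps
    nHi <- sum(tHi >= ev$start_s[e] & tHi < ev$end_s[e])
    nLo <- sum(tLo >= ev$start_s[e] & tLo < ev$end_s[e])
    d <- ev$end_s[e] - ev$start_s[e]
    expect_lte(abs(nHi - floor(d * 100)), 1)
    expect_lte(abs(nLo - floor(d)), 1)
  }
  # events enumerate the catalogue in protocol order
  expect_identical(ev$state, tinyCatalogue(3)$state)
})

test_that("generation is a pure function of (config, dogId, seed)", {
  cfg <- cohortConfig(nDogs = 1, catalogue = tinyCatalogue(3),
                      durationRange = c(1, 2), masterSeed = 9)
  a <- generateSession(cfg, "d1", 42)
  b <- generateSession(cfg, "d1", 42)
  for (m in c("imu", "audio", "light", "temperature", "humidity", "pressure"))
    expect_identical(sessionStream(a, m)@values, sessionStream(b, m)@values)
  expect_identical(sessionEvents(a), sessionEvents(b))
})

test_that("cohort sessions have unique ids and differing per-dog streams", {
  coh <- tinyCohort(nDogs = 3, normalize = FALSE)
  expect_length(coh, 3)
  ids <- vapply(coh, dogId, character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_false(isTRUE(all.equal(sessionStream(coh[[1]], "imu")@values[1:100, ],
                                sessionStream(coh[[2]], "imu")@values[1:100, ])))
})

test_that("a large cohort with short events completes", {
  cfg <- cohortConfig(nDogs = 460, catalogue = tinyCatalogue(2),
                      durationRange = c(0.5, 1), masterSeed = 3)
  coh <- generateCohort(cfg)
  expect_length(coh, 460)
  expect_length(unique(vapply(coh, dogId, character(1))), 460)
})

test_that("noise-free IMU spectra peak at the motif frequency", {
  freqs <- c(2, 6, 11)
  cfg <- cohortConfig(nDogs = 1, catalogue = tinyCatalogue(3, freqs = freqs),
                      durationRange = c(4, 4), noiseScale = 0, masterSeed = 2)
  s <- generateSession(cfg, "d1", 8)
  ev <- sessionEvents(s)
  tHi <- sessionStream(s, "imu")@timestamps
  for (e in seq_len(nrow(ev))) {
    sel <- tHi >= ev$start_s[e] & tHi < ev$end_s[e]
    x <- sessionStream(s, "imu")@values[sel, 1]
    sp <- Mod(fft(x - mean(x)))[2:(floor(length(x) / 2))]
    fDom <- which.max(sp) / (length(x) / 100)    # Hz
    expect_lt(abs(fDom - freqs[e]), 0.5)
  }
})

test_that("audio bursts concentrate in high-burst-probability states", {
  cat2 <- tinyCatalogue(2, burst = 0)
  cat2$audioBurstProb <- c(0.9, 0)
  cfg <- cohortConfig(nDogs = 1, catalogue = cat2, durationRange = c(8, 8),
                      masterSeed = 4)
  s <- generateSession(cfg, "d1", 6)
  ev <- sessionEvents(s)
  au <- sessionStream(s, "audio")
  m1 <- max(au@values[au@timestamps < ev$end_s[1]])
  m2 <- max(au@values[au@timestamps >= ev$start_s[2]])
  expect_gt(m1, m2 + 5)  # burst spikes tower over the quiet state
})

test_that("session export/import round-trips within tolerance", {
  coh <- tinyCohort(nDogs = 1, normalize = FALSE)
  s <- coh[[1]]
  dir <- file.path(tempdir(), "sess1")
  files <- exportSession(s, dir)
  expect_length(files, 7)
  s2 <- importSession(dir)
  for (m in c("imu", "audio", "light", "temperature", "humidity", "pressure")) {
    expect_equal(sessionStream(s2, m)@values,
                 sessionStream(s, m)@values, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sessionStream(s2, m)@timestamps,
                 sessionStream(s, m)@timestamps, tolerance = 1e-9)
  }
  expect_identical(sessionEvents(s2)$state, sessionEvents(s)$state)

  # re-export is byte-identical
  dir2 <- file.path(tempdir(), "sess2")
  exportSession(s, dir2)
  for (f in list.files(dir, full.names = TRUE))
    expect_identical(readLines(f), readLines(file.path(dir2, basename(f))))
})

test_that("import rejects broken layouts instead of truncating silently", {
  coh <- tinyCohort(nDogs = 1, k = 2, normalize = FALSE)
  dir <- file.path(tempdir(), "sessbad")
  exportSession(coh[[1]], dir)

  unlink(file.path(dir, "humidity.csv"))
  expect_error(importSession(dir), "humidity")
  exportSession(coh[[1]], dir)

  # corrupt a row (missing field)
  p <- file.path(dir, "temperature.csv")
  lines <- readLines(p)
  lines[2] <- "0"
  writeLines(lines, p)
  expect_error(importSession(dir), "corrupt")
  exportSession(coh[[1]], dir)

  # out-of-order events: resorted by default, rejected in strict mode
  pe <- file.path(dir, "events.csv")
  ev <- read.csv(pe)
  write.csv(ev[rev(seq_len(nrow(ev))), ], pe, row.names = FALSE)
  expect_error(importSession(dir, strict = TRUE), "out of order")
  s2 <- importSession(dir, strict = FALSE)
  expect_false(is.unsorted(sessionEvents(s2)$start_s))
})

test_that("generator rejects invalid configurations", {
  expect_error(cohortConfig(nDogs = 0), "nDogs")
  expect_error(cohortConfig(durationRange = c(-1, 2)), "durationRange")
  cfg <- cohortConfig(nDogs = 1, catalogue = tinyCatalogue(2))
  expect_error(generateSession(cfg, "d1", 1, states = c("S1", "nope")),
               "unknown state")
})
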