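ENV_BASE <- c(light = 300, temperature = 22, humidity = 45, pressure = 1013)
ENV_DRIFT_SCALE <- c(light = 20, temperature = 1, humidity = 2, pressure = 0.5)
ENV_NOISE_SD <- c(light = 1, temperature = 0.02, humidity = 0.05, pressure = 0.02)
AUDIO_BASE_DB <- 40
AUDIO_BURST_DB <- 25
AUDIO_BURST_TAU <- 0.15
AUDIO_NOISE_SD <- 0.5
IMU_AXIS_GAIN <- c(1, 0.8, 0.6)
IMU_AXIS_PHASE <- c(0, 2 * pi / 3, 4 * pi / 3)
JERK_FREQ_HZ <- 22       # high-frequency component carrying "jerkiness"
JERK_REL_AMP <- 0.3      # relative to the motif amplitude, per unit jerk factor

#' Generate one labelled synthetic collar session
#'
#' Simulates a single dog's scripted evaluation run: the catalogue states are
#' visited sequentially in protocol order, each for a duration drawn uniformly
#' from the configured range, back to back. Inertial channels follow the
#' state's motif (base + amplitude * sin(2 pi f t + phase) + a jerk-scaled
#' high-frequency term + Gaussian noise, with fixed per-axis gains and phase
#' offsets); the audio channel is a baseline decibel level with exponentially
#' decaying burst spikes whose per-second probability is the state's
#' `audioBurstProb`; light, temperature, humidity and pressure drift slowly
#' with tiny noise. Identical `(config, dogId, seed)` yield bit-identical
#' sessions.
#'
#' @param config A [CohortConfig-class].
#' @param dogId Dog identifier string.
#' @param seed Non-negative integer seed.
#' @param states Optional state order; defaults to the catalogue's protocol
#'   order. All names must exist in the catalogue.
#' @return A [CollarSession-class].
#' @examples
#' cfg <- cohortConfig(nDogs = 1, durationRange = c(1, 2))
#' s <- generateSession(cfg, "dog001", seed = 7)
#' nrow(sessionEvents(s))
#' @export
generateSession <- function(config, dogId, seed, states = NULL) {
  stopIfNot(is(config, "CohortConfig"), "config must be a CohortConfig")
  validObject(config)
  cat_ <- config@catalogue
  if (is.null(states)) states <- cat_$state
  unknown <- setdiff(states, cat_$state)
  stopIfNot(length(unknown) == 0L,
            paste("unknown state(s) in catalogue:", paste(unknown, collapse = ", ")))
  idx <- match(states, cat_$state)
  nEv <- length(idx)

  withSeed(seed, {
    durations <- runif(nEv, config@durationRange[1], config@durationRange[2])
    ends <- cumsum(durations)
    starts <- c(0, head(ends, -1))
    durationS <- ends[nEv]
    events <- data.frame(state = states, start_s = starts, end_s = ends,
                         stringsAsFactors = FALSE)

    phases <- runif(nEv, 0, 2 * pi)
    driftSigns <- sample(c(-1, 1), nEv, replace = TRUE)

    nHi <- floor(durationS * 100) + 1    # cover the full span incl. both ends
    tHi <- (seq_len(nHi) - 1) / 100
    nLo <- floor(durationS) + 1
    tLo <- seq_len(nLo) - 1
    evHi <- findInterval(tHi, starts)            # event index per high-rate sample
    evLo <- findInterval(tLo, starts)

    ns <- config@noiseScale
    p <- cat_[idx, ]

    # --- IMU: 3 axes ------------------------------------------------------
    carrier <- 2 * pi * p$frequency[evHi] * tHi + phases[evHi]
    jerkCar <- 2 * pi * JERK_FREQ_HZ * tHi
    imu <- matrix(0, nHi, 3)
    for (a in 1:3) {
      det <- p$base[evHi] + IMU_AXIS_GAIN[a] *
        (p$amplitude[evHi] * sin(carrier + IMU_AXIS_PHASE[a]) +
           JERK_REL_AMP * p$jerkFactor[evHi] * p$amplitude[evHi] *
             sin(jerkCar + IMU_AXIS_PHASE[a]))
      imu[, a] <- det + rnorm(nHi, 0, 1) * p$noiseSd[evHi] * ns
    }
    colnames(imu) <- c("x", "y", "z")

    # --- Audio: baseline + sustained state level + decaying bursts --------
    audio <- AUDIO_BASE_DB + p$audioLevel[evHi] +
      rnorm(nHi, 0, AUDIO_NOISE_SD * ns)
    for (e in seq_len(nEv)) {
      secs <- seq(floor(starts[e]), ceiling(ends[e]) - 1)
      fire <- runif(length(secs)) < p$audioBurstProb[e]
      offs <- runif(length(secs))
      for (k in which(fire)) {
        t0 <- secs[k] + offs[k]
        if (t0 < starts[e] || t0 >= ends[e]) next
        win <- which(tHi >= t0 & tHi < t0 + 1)
        audio[win] <- audio[win] + AUDIO_BURST_DB * exp(-(tHi[win] - t0) / AUDIO_BURST_TAU)
      }
    }
    audio <- matrix(audio, ncol = 1, dimnames = list(NULL, "db"))

    # --- Environmental channels: base + slow state-paced drift ------------
    envSeries <- function(tt, evIdx, mod) {
      rate <- driftSigns[evIdx] * p$envDriftRate[evIdx] * ENV_DRIFT_SCALE[[mod]]
      dt <- diff(c(0, tt))
      drift <- cumsum(rate * dt)
      v <- ENV_BASE[[mod]] + drift + rnorm(length(tt), 0, ENV_NOISE_SD[[mod]] * ns)
      matrix(v, ncol = 1, dimnames = list(NULL, mod))
    }
    light <- envSeries(tHi, evHi, "light")
    temperature <- envSeries(tLo, evLo, "temperature")
    humidity <- envSeries(tLo, evLo, "humidity")
    pressure <- envSeries(tLo, evLo, "pressure")

    streams <- list(
      imu = new("SensorStream", modality = "imu", rateHz = 100,
                timestamps = tHi, values = imu),
      audio = new("SensorStream", modality = "audio", rateHz = 100,
                  timestamps = tHi, values = audio),
      light = new("SensorStream", modality = "light", rateHz = 100,
                  timestamps = tHi, values = light),
      temperature = new("SensorStream", modality = "temperature", rateHz = 1,
                        timestamps = tLo, values = temperature),
      humidity = new("SensorStream", modality = "humidity", rateHz = 1,
                     timestamps = tLo, values = humidity),
      pressure = new("SensorStream", modality = "pressure", rateHz = 1,
                     timestamps = tLo, values = pressure))

    new("CollarSession", dogId = as.character(dogId), seed = as.numeric(seed),
        streams = streams, events = events, durationS = durationS,
        normalized = FALSE)
  })
}

#' Generate a cohort of synthetic sessions
#'
#' Per-dog seeds are derived deterministically from the master seed with a
#' multiplicative counter hash, so individual sessions can be regenerated
#' independently and the whole cohort is reproducible.
#'
#' @param config A [CohortConfig-class].
#' @param states Optional state order passed to [generateSession()].
#' @return List of [CollarSession-class], one per dog, with unique dog ids.
#' @examples
#' cfg <- cohortConfig(nDogs = 2, durationRange = c(1, 2))
#' length(generateCohort(cfg))
#' @export
generateCohort <- function(config, states = NULL) {
  stopIfNot(is(config, "CohortConfig"), "config must be a CohortConfig")
  validObject(config)
  n <- as.integer(config@nDogs)
  lapply(seq_len(n), function(d) {
    generateSession(config, sprintf("dog%03d", d),
                    deriveSeed(config@masterSeed, d), states = states)
  })
}
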