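#' @import methods
NULL

MODALITIES <- c("imu", "audio", "light", "temperature", "humidity", "pressure")
HIGH_RATE_MODALITIES <- c("imu", "audio", "light")
MODALITY_CHANNELS <- c(imu = 3L, audio = 1L, light = 1L,
                       temperature = 1L, humidity = 1L, pressure = 1L)
MODALITY_RATE <- c(imu = 100, audio = 100, light = 100,
                   temperature = 1, humidity = 1, pressure = 1)

# Fixed channel stacking order for fused samples.
CHANNEL_ORDER <- c("imu.x", "imu.y", "imu.z", "audio", "light",
                   "temperature", "humidity", "pressure")

FUSIONS <- c("IMU", "IMU-Audio", "IMU-Audio-Env")

#' Channels selected by a fusion group
#'
#' The three fusion groups combine the inertial axes alone (3 channels), with
#' the audio level (4), or with audio plus the four environmental channels —
#' ambient light, temperature, relative humidity and barometric pressure (8).
#'
#' @param fusion One of `"IMU"`, `"IMU-Audio"`, `"IMU-Audio-Env"`.
#' @return Character vector of channel names in stacking order.
#' @examples
#' fusionChannels("IMU-Audio-Env")
#' @export
fusionChannels <- function(fusion) {
  fusion <- match.arg(fusion, FUSIONS)
  switch(fusion,
         "IMU" = CHANNEL_ORDER[1:3],
         "IMU-Audio" = CHANNEL_ORDER[1:4],
         "IMU-Audio-Env" = CHANNEL_ORDER)
}

#' SensorStream: one modality's time series
#'
#' A single modality recorded over a session: strictly increasing timestamps
#' (seconds) and a timestamps-by-channels value matrix. Inertial, audio and
#' light channels are sampled at 100 Hz; temperature, humidity and pressure at
#' 1 Hz.
#'
#' @slot modality One of `imu`, `audio`, `light`, `temperature`, `humidity`,
#'   `pressure`.
#' @slot rateHz Nominal sampling rate (100 or 1).
#' @slot timestamps Numeric vector, seconds from session start.
#' @slot values Numeric matrix, `length(timestamps)` rows.
#' @export
setClass("SensorStream", representation(
  modality = "character", rateHz = "numeric",
  timestamps = "numeric", values = "matrix"))

setValidity("SensorStream", function(object) {
  msgs <- character()
  if (!object@modality %in% MODALITIES)
    msgs <- c(msgs, sprintf("unknown modality '%s'", object@modality))
  else {
    if (object@rateHz != MODALITY_RATE[[object@modality]])
      msgs <- c(msgs, sprintf("modality '%s' must be sampled at %g Hz",
                              object@modality, MODALITY_RATE[[object@modality]]))
    if (ncol(object@values) != MODALITY_CHANNELS[[object@modality]])
      msgs <- c(msgs, sprintf("modality '%s' must have %d channel(s)",
                              object@modality, MODALITY_CHANNELS[[object@modality]]))
  }
  if (length(object@timestamps) != nrow(object@values))
    msgs <- c(msgs, "timestamps length must equal rows of values")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' CollarSession: one dog's labelled multi-rate recording
#'
#' Holds the six sensor streams of one evaluation run together with the event
#' log of labelled state intervals recorded by the trainer.
#'
#' @slot dogId Dog identifier.
#' @slot seed Seed the session was generated from (`NA` for imported data).
#' @slot streams Named list with one [SensorStream-class] per modality.
#' @slot events `data.frame` with columns `state`, `start_s`, `end_s`;
#'   time-ordered, non-overlapping, inside `[0, durationS]`.
#' @slot durationS Session length in seconds.
#' @slot normalized Whether per-modality Z-normalisation has been applied.
#' @export
setClass("CollarSession", representation(
  dogId = "character", seed = "numeric", streams = "list",
  events = "data.frame", durationS = "numeric", normalized = "logical"))

setValidity("CollarSession", function(object) {
  msgs <- character()
  if (!setequal(names(object@streams), MODALITIES))
    msgs <- c(msgs, "streams must contain exactly the six modalities")
  ev <- object@events
  if (!all(c("state", "start_s", "end_s") %in% names(ev)))
    msgs <- c(msgs, "events must have columns state, start_s, end_s")
  else if (nrow(ev)) {
    if (any(ev$start_s >= ev$end_s)) msgs <- c(msgs, "events must have start_s < end_s")
    if (any(ev$start_s < 0) || any(ev$end_s > object@durationS + 1e-9))
      msgs <- c(msgs, "events must fall within [0, durationS]")
    if (nrow(ev) > 1L && any(ev$start_s[-1] < ev$end_s[-nrow(ev)] - 1e-9))
      msgs <- c(msgs, "events must be time-ordered and non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CollarSession", function(object) {
  cat(sprintf("CollarSession '%s': %.1f s, %d events, %s\n",
              object@dogId, object@durationS, nrow(object@events),
              if (object@normalized) "Z-normalized" else "raw"))
  for (m in MODALITIES) {
    s <- object@streams[[m]]
    cat(sprintf("  %-11s %g Hz, %d x %d\n", m, s@rateHz,
                nrow(s@values), ncol(s@values)))
  }
})

#' @describeIn CollarSession-class Event log accessor.
#' @param session A [CollarSession-class].
#' @export
sessionEvents <- function(session) session@events

#' @describeIn CollarSession-class Stream accessor.
#' @param modality Modality name.
#' @export
sessionStream <- function(session, modality) {
  modality <- match.arg(modality, MODALITIES)
  session@streams[[modality]]
}

#' @describeIn CollarSession-class Dog identifier accessor.
#' @export
dogId <- function(session) session@dogId

#' CohortConfig: generator settings for a synthetic cohort
#'
#' @slot nDogs Number of dogs to simulate.
#' @slot catalogue State motif catalogue (see [defaultStateCatalogue()]).
#' @slot durationRange Per-event duration range in seconds; with the default
#'   50-state catalogue and U(8, 16) s events a session lasts about ten
#'   minutes.
#' @slot noiseScale Global multiplier on all motif noise levels.
#' @slot masterSeed Master seed; per-dog seeds are derived deterministically.
#' @export
setClass("CohortConfig", representation(
  nDogs = "numeric", catalogue = "data.frame", durationRange = "numeric",
  noiseScale = "numeric", masterSeed = "numeric"))

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@nDogs < 1) msgs <- c(msgs, "nDogs must be >= 1")
  if (length(object@durationRange) != 2L ||
      any(object@durationRange <= 0) ||
      object@durationRange[1] > object@durationRange[2])
    msgs <- c(msgs, "durationRange must be two positive increasing values")
  if (object@noiseScale < 0) msgs <- c(msgs, "noiseScale must be >= 0")
  ok <- tryCatch({ validateCatalogue(object@catalogue); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (length(msgs)) msgs else TRUE
})

#' Construct a cohort configuration
#'
#' @param nDogs Number of dogs (default 20).
#' @param catalogue Motif catalogue; default [defaultStateCatalogue()].
#' @param durationRange Per-event duration range (s), default `c(8, 16)`.
#' @param noiseScale Global noise multiplier, default 1.
#' @param masterSeed Master seed, default 1.
#' @return A [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nDogs = 2, durationRange = c(1, 2))
#' @export
cohortConfig <- function(nDogs = 20, catalogue = defaultStateCatalogue(),
                         durationRange = c(8, 16), noiseScale = 1,
                         masterSeed = 1) {
  new("CohortConfig", nDogs = nDogs, catalogue = catalogue,
      durationRange = as.numeric(durationRange), noiseScale = noiseScale,
      masterSeed = masterSeed)
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d dogs, %d states, events U(%g, %g) s, seed %g\n",
              as.integer(object@nDogs), nrow(object@catalogue),
              object@durationRange[1], object@durationRange[2],
              object@masterSeed))
})
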