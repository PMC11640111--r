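#' Default 50-state motif catalogue
#'
#' Builds the default catalogue of 50 named behavioural states used by the
#' session generator. Each state is a motion motif: a per-channel base level,
#' an oscillation amplitude (in g) and frequency (Hz), a Gaussian noise level,
#' a dimensionless jerk factor scaling a high-frequency component (erratic,
#' excitable movement shows up as jerkiness in collar inertial data), a
#' per-second probability of a loud audio burst (noise-distraction states such
#' as a vacuum cleaner turning on or a metal can being shaken), and a slow
#' drift rate for the environmental channels.
#'
#' The protocol runs the states sequentially in catalogue order. A subset of
#' states is deliberately well separated in frequency/amplitude space while the
#' remainder crowd a narrow band — real evaluation protocols likewise contain
#' both highly distinctive stimuli and many near-identical ones, which is what
#' drives the 10-state "most distinguishable" selection downstream.
#'
#' @return A `data.frame` with 50 rows and columns `state`, `base`,
#'   `amplitude`, `frequency`, `noiseSd`, `jerkFactor`, `audioBurstProb`,
#'   `audioLevel` (sustained dB offset during the state), `envDriftRate`.
#' @examples
#' cat50 <- defaultStateCatalogue()
#' nrow(cat50)
#' @export
defaultStateCatalogue <- function() {
  states <- c(
    "Idle", "Leash on", "Explore-Enters Space", "Ignore dog", "Handler returns",
    "Vacuum on-On leash", "Vacuum passes", "Noise can shake", "Noise can drop",
    "Food bowl drop", "Umbrella opens", "Umbrella closes", "Fan passes",
    "Fan stationary", "Sees distraction dog", "Dog dist-Approach",
    "Dog dist-Dog returns to handler", "Dog dist-Walks past", "Sees Unusual Person",
    "Unusual person approaches", "Sees bat", "Rolly toy seen", "Rolly toy passes",
    "Stairs up", "Stairs down", "Walk on leash", "Trot on leash", "Heel practice",
    "Sit command", "Down command", "Stay command", "Recall", "Exam-load on table",
    "Dog on table", "Vet arrives", "Exam body check", "Exam paw handling",
    "Exam complete", "Off table", "Doorway pause", "Tight space pass",
    "Grate crossing", "Traffic sound playback", "Crowd walk", "Obstacle weave",
    "Curb stop", "Treat refusal", "Water bowl offered", "Kennel entry", "Kennel rest"
  )
  stopifnot(length(states) == 50L, !anyDuplicated(states))

  n <- 50L
  # crowded defaults: similar mid-band motion, mild noise
  base <- rep_len(c(0.05, 0.10, -0.05, 0.15, 0.00), n)
  amplitude <- rep_len(c(0.55, 0.65, 0.50, 0.70, 0.60), n)
  frequency <- 1.8 + 0.04 * (seq_len(n) - 1)            # 1.80 .. 3.76 Hz band
  noiseSd <- rep_len(c(0.30, 0.25, 0.35, 0.28, 0.32), n)
  jerkFactor <- rep_len(c(0.4, 0.8, 0.2, 0.6, 1.0), n)
  audioBurstProb <- rep_len(c(0.02, 0.05, 0.03, 0.04, 0.02), n)
  audioLevel <- rep_len(c(0, 2, 1, 0, 1), n)
  envDriftRate <- rep_len(c(0.002, 0.004, 0.001, 0.003, 0.002), n)

  # distinctive states: widely spaced frequencies, larger amplitude, low noise
  distinct <- c("Idle", "Vacuum on-On leash", "Noise can shake", "Umbrella opens",
                "Fan passes", "Explore-Enters Space", "Trot on leash",
                "Dog dist-Dog returns to handler", "Sees Unusual Person",
                "Exam complete", "Stairs up", "Recall")
  iD <- match(distinct, states)
  frequency[iD] <- c(0.4, 6.5, 8.0, 9.5, 11.0, 1.0, 4.6, 5.5, 12.5, 0.7, 3.4, 14.0)
  amplitude[iD] <- c(0.15, 1.8, 2.2, 1.6, 2.0, 1.2, 1.5, 1.7, 2.4, 0.25, 1.4, 2.1)
  base[iD] <- c(0.00, 0.30, -0.20, 0.25, -0.15, 0.10, 0.05, 0.20, -0.10, 0.02, 0.35, -0.30)
  noiseSd[iD] <- 0.08
  jerkFactor[iD] <- c(0.0, 1.8, 2.0, 1.2, 1.5, 0.3, 0.8, 1.0, 1.6, 0.1, 0.6, 1.9)

  # noise-distraction states: frequent loud bursts, and a sustained elevated
  # sound level for machinery that runs through the whole state
  bursty <- c("Vacuum on-On leash", "Vacuum passes", "Noise can shake",
              "Noise can drop", "Food bowl drop", "Umbrella opens", "Fan passes",
              "Traffic sound playback")
  audioBurstProb[match(bursty, states)] <- 0.7
  sustained <- c("Vacuum on-On leash" = 20, "Vacuum passes" = 15,
                 "Fan passes" = 15, "Fan stationary" = 12,
                 "Traffic sound playback" = 10, "Noise can shake" = 8)
  audioLevel[match(names(sustained), states)] <- sustained

  data.frame(state = states, base = base, amplitude = amplitude,
             frequency = frequency, noiseSd = noiseSd, jerkFactor = jerkFactor,
             audioBurstProb = audioBurstProb, audioLevel = audioLevel,
             envDriftRate = envDriftRate, stringsAsFactors = FALSE)
}

validateCatalogue <- function(catalogue) {
  req <- c("state", "base", "amplitude", "frequency", "noiseSd", "jerkFactor",
           "audioBurstProb", "audioLevel", "envDriftRate")
  stopIfNot(is.data.frame(catalogue) && all(req %in% names(catalogue)),
            paste("catalogue must be a data.frame with columns:",
                  paste(req, collapse = ", ")))
  stopIfNot(nrow(catalogue) >= 1L, "catalogue must contain at least one state")
  stopIfNot(!anyDuplicated(catalogue$state), "state names must be unique")
  stopIfNot(all(catalogue$noiseSd >= 0), "noiseSd must be >= 0")
  stopIfNot(all(catalogue$frequency >= 0), "frequency must be >= 0")
  stopIfNot(all(catalogue$audioBurstProb >= 0 & catalogue$audioBurstProb <= 1),
            "audioBurstProb must lie in [0, 1]")
  invisible(catalogue)
}
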