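GRID_LEN <- 500L     # fixed per-event grid length after interpolation
WINDOW_LEN <- 25L    # subsample window length
N_WINDOWS <- 20L     # windows per aligned event (500 / 25)

# channel name -> (modality, column)
CHANNEL_MAP <- list(
  "imu.x" = c("imu", 1L), "imu.y" = c("imu", 2L), "imu.z" = c("imu", 3L),
  "audio" = c("audio", 1L), "light" = c("light", 1L),
  "temperature" = c("temperature", 1L), "humidity" = c("humidity", 1L),
  "pressure" = c("pressure", 1L))

#' AlignedSequence: one event on the common 500-sample grid
#'
#' @slot label State name of the event.
#' @slot values 500 x C numeric matrix (C = channels of the chosen fusion).
#' @slot channels Channel names in stacking order.
#' @slot dogId,eventIndex Provenance.
#' @export
setClass("AlignedSequence", representation(
  label = "character", values = "matrix", channels = "character",
  dogId = "character", eventIndex = "integer"))

setValidity("AlignedSequence", function(object) {
  msgs <- character()
  if (nrow(object@values) != GRID_LEN)
    msgs <- c(msgs, sprintf("values must have exactly %d rows", GRID_LEN))
  if (anyNA(object@values)) msgs <- c(msgs, "values must not contain NA")
  if (ncol(object@values) != length(object@channels))
    msgs <- c(msgs, "channel names must match value columns")
  if (length(msgs)) msgs else TRUE
})

#' WindowSample: one 25-sample window of an aligned event
#'
#' @slot label State name.
#' @slot values 25 x C numeric matrix.
#' @slot channels Channel names.
#' @slot dogId,eventIndex Parent provenance.
#' @slot windowIndex Window position within the parent, 0..19.
#' @export
setClass("WindowSample", representation(
  label = "character", values = "matrix", channels = "character",
  dogId = "character", eventIndex = "integer", windowIndex = "integer"))

setValidity("WindowSample", function(object) {
  msgs <- character()
  if (nrow(object@values) != WINDOW_LEN)
    msgs <- c(msgs, sprintf("values must have exactly %d rows", WINDOW_LEN))
  if (object@windowIndex < 0L || object@windowIndex >= N_WINDOWS)
    msgs <- c(msgs, sprintf("windowIndex must lie in [0, %d]", N_WINDOWS - 1L))
  if (length(msgs)) msgs else TRUE
})

#' Z-normalize a session per modality
#'
#' Standardises each sensor modality using its mean and population standard
#' deviation over the entire session (all channels of a modality pooled, so
#' the three inertial axes share one mu/sigma). A modality with zero variance
#' is set identically to 0 with a warning.
#'
#' @param session A [CollarSession-class].
#' @return A list with elements `session` (normalized copy) and `stats`
#'   (`data.frame` with columns `modality`, `mu`, `sigma`).
#' @examples
#' cfg <- cohortConfig(nDogs = 1, durationRange = c(1, 2))
#' z <- znormalizeSession(generateSession(cfg, "d1", 1))
#' z$stats
#' @export
znormalizeSession <- function(session) {
  stopIfNot(is(session, "CollarSession"), "session must be a CollarSession")
  stats <- data.frame(modality = MODALITIES, mu = NA_real_, sigma = NA_real_,
                      stringsAsFactors = FALSE)
  out <- session
  for (i in seq_along(MODALITIES)) {
    m <- MODALITIES[i]
    v <- session@streams[[m]]@values
    stopIfNot(length(v) >= 1L, paste("modality", m, "has no samples"))
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2))    # population SD
    stats$mu[i] <- mu
    stats$sigma[i] <- sigma
    if (sigma > 0) {
      out@streams[[m]]@values <- (v - mu) / sigma
    } else {
      warning("modality '", m, "' is constant; set to 0", call. = FALSE)
      out@streams[[m]]@values <- v * 0
    }
  }
  out@normalized <- TRUE
  list(session = out, stats = stats)
}

#' Interpolate one event onto the 500-sample grid
#'
#' Resamples every channel of the chosen fusion by piecewise-linear
#' interpolation onto 500 equally spaced times spanning the event; the first
#' and last grid points coincide with the event boundaries (values beyond the
#' outermost in-event samples are held constant). A low-rate channel with a
#' single in-event sample becomes a constant channel at that value.
#'
#' @param session A [CollarSession-class].
#' @param event Integer index into `sessionEvents(session)`.
#' @param fusion Fusion group, see [fusionChannels()].
#' @return An [AlignedSequence-class] (500 x C).
#' @export
interpolateEvent <- function(session, event, fusion = "IMU") {
  stopIfNot(is(session, "CollarSession"), "session must be a CollarSession")
  ev <- session@events
  stopIfNot(is.numeric(event) && length(event) == 1L &&
              event >= 1 && event <= nrow(ev),
            "event must be a single valid event index")
  event <- as.integer(event)
  chans <- fusionChannels(fusion)
  start <- ev$start_s[event]; end <- ev$end_s[event]
  grid <- seq(start, end, length.out = GRID_LEN)
  out <- matrix(NA_real_, GRID_LEN, length(chans),
                dimnames = list(NULL, chans))
  for (j in seq_along(chans)) {
    mc <- CHANNEL_MAP[[chans[j]]]
    s <- session@streams[[mc[1]]]
    sel <- s@timestamps >= start & s@timestamps <= end
    n <- sum(sel)
    if (n == 0L)
      stop(sprintf("event %d ('%s'): no samples in modality '%s' window",
                   event, ev$state[event], mc[1]), call. = FALSE)
    ts <- s@timestamps[sel]
    vs <- s@values[sel, as.integer(mc[2])]
    if (s@rateHz >= 100 && n < 2L)
      stop(sprintf("event %d ('%s'): fewer than 2 samples in high-rate modality '%s'",
                   event, ev$state[event], mc[1]), call. = FALSE)
    out[, j] <- if (n == 1L) rep(vs, GRID_LEN)
                else approx(ts, vs, xout = grid, rule = 2)$y
  }
  new("AlignedSequence", label = ev$state[event], values = out,
      channels = chans, dogId = session@dogId, eventIndex = event)
}

#' Split an aligned event into 20 windows of 25 samples
#'
#' Contiguous, non-overlapping, order-preserving: window `k` holds rows
#' `[25k, 25k+25)` and the concatenation of all windows reproduces the input
#' exactly.
#'
#' @param aligned An [AlignedSequence-class] (or a 500 x C matrix).
#' @return A list of 20 [WindowSample-class] objects (or 25 x C matrices when
#'   the input is a plain matrix).
#' @export
windowSequence <- function(aligned) {
  mat <- if (is(aligned, "AlignedSequence")) aligned@values else aligned
  stopIfNot(is.matrix(mat), "input must be an AlignedSequence or a matrix")
  if (nrow(mat) %% WINDOW_LEN != 0L)
    stop("row count ", nrow(mat), " is not divisible by ", WINDOW_LEN,
         call. = FALSE)
  nW <- nrow(mat) %/% WINDOW_LEN
  lapply(seq_len(nW) - 1L, function(k) {
    rows <- (k * WINDOW_LEN + 1L):((k + 1L) * WINDOW_LEN)
    w <- mat[rows, , drop = FALSE]
    if (is(aligned, "AlignedSequence"))
      new("WindowSample", label = aligned@label, values = w,
          channels = aligned@channels, dogId = aligned@dogId,
          eventIndex = aligned@eventIndex, windowIndex = k)
    else w
  })
}

#' Select the k most distinguishable states from a confusion matrix
#'
#' Ranks states by per-class recall (diagonal count over row sum; 0 for a
#' state that never occurs) and returns the top `k`, breaking ties
#' lexicographically by state name.
#'
#' @param cm Square confusion matrix with state names as dimnames
#'   (rows = true).
#' @param k Number of states to keep.
#' @return Character vector of `k` state names.
#' @export
selectTopStates <- function(cm, k) {
  stopIfNot(is.matrix(cm) && nrow(cm) == ncol(cm), "cm must be square")
  K <- nrow(cm)
  stopIfNot(k >= 1 && k <= K, "k must satisfy 1 <= k <= nrow(cm)")
  rs <- rowSums(cm)
  recall <- ifelse(rs > 0, diag(cm) / rs, 0)
  nm <- rownames(cm)
  ord <- order(-recall, nm)
  nm[ord][seq_len(k)]
}
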