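#' SensorVariant: fixed-shape labelled samples for one grid cell
#'
#' One cell of the (sampling x state-count x fusion) experiment grid: a stack
#' of fixed-shape samples (500 x C aligned events or 25 x C windows) with
#' their labels, vocabulary and provenance.
#'
#' @slot sampling `"interpolate"` (one 500 x C sample per event) or
#'   `"subsample"` (twenty 25 x C windows per event).
#' @slot nStates Vocabulary size (10 or 50 in the default grid).
#' @slot fusion Fusion group name.
#' @slot samples Numeric array `n x T x C`.
#' @slot labels Character vector of length `n`.
#' @slot vocabulary Character vector of `nStates` state names.
#' @slot provenance `data.frame` with `dogId`, `eventIndex`, `windowIndex`
#'   (`NA` for interpolate samples).
#' @export
setClass("SensorVariant", representation(
  sampling = "character", nStates = "integer", fusion = "character",
  samples = "array", labels = "character", vocabulary = "character",
  provenance = "data.frame"))

setValidity("SensorVariant", function(object) {
  msgs <- character()
  d <- dim(object@samples)
  if (length(d) != 3L) msgs <- c(msgs, "samples must be an n x T x C array")
  else {
    expT <- if (object@sampling == "interpolate") GRID_LEN else WINDOW_LEN
    if (d[2] != expT)
      msgs <- c(msgs, sprintf("sampling '%s' requires T = %d", object@sampling, expT))
    if (d[3] != length(fusionChannels(object@fusion)))
      msgs <- c(msgs, "channel count must match fusion group")
    if (d[1] != length(object@labels) || d[1] != nrow(object@provenance))
      msgs <- c(msgs, "labels/provenance must align with samples")
  }
  if (!object@sampling %in% c("interpolate", "subsample"))
    msgs <- c(msgs, "sampling must be 'interpolate' or 'subsample'")
  if (length(object@vocabulary) != object@nStates)
    msgs <- c(msgs, "vocabulary size must equal nStates")
  if (!all(object@labels %in% object@vocabulary))
    msgs <- c(msgs, "all labels must be in the vocabulary")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SensorVariant", function(object) {
  d <- dim(object@samples)
  cat(sprintf("SensorVariant: %s / %d states / %s — %d samples of %d x %d\n",
              object@sampling, object@nStates, object@fusion, d[1], d[2], d[3]))
})

#' @describeIn SensorVariant-class Number of samples.
#' @param variant A [SensorVariant-class].
#' @export
nSamples <- function(variant) dim(variant@samples)[1]

#' @describeIn SensorVariant-class Sample array accessor (`n x T x C`).
#' @export
sampleArray <- function(variant) variant@samples

#' @describeIn SensorVariant-class Label accessor.
#' @export
sampleLabels <- function(variant) variant@labels

#' @describeIn SensorVariant-class Vocabulary accessor.
#' @export
variantVocabulary <- function(variant) variant@vocabulary

#' @describeIn SensorVariant-class Flatten samples to an `n x (T*C)` matrix
#'   (time index fastest), the layout used by the kernel PCA classifier.
#' @export
flattenSamples <- function(variant) {
  d <- dim(variant@samples)
  matrix(variant@samples, d[1], d[2] * d[3])
}

#' @describeIn SensorVariant-class Subset a variant by sample index.
#' @param idx Integer vector of sample indices.
#' @export
variantSubset <- function(variant, idx) {
  new("SensorVariant", sampling = variant@sampling, nStates = variant@nStates,
      fusion = variant@fusion,
      samples = variant@samples[idx, , , drop = FALSE],
      labels = variant@labels[idx], vocabulary = variant@vocabulary,
      provenance = variant@provenance[idx, , drop = FALSE])
}

#' Build one dataset variant from Z-normalized sessions
#'
#' Emits one aligned sample per event (`sampling = "interpolate"`) or twenty
#' 25-sample windows per event (`"subsample"`), restricted to the requested
#' state subset; the subsample variant therefore holds exactly 20x the
#' samples of the interpolate variant built from the same sessions.
#'
#' @param sessions List of [CollarSession-class], already Z-normalized (a
#'   warning is issued otherwise).
#' @param sampling `"interpolate"` or `"subsample"`.
#' @param nStates Vocabulary size; if 10 (or any value below the number of
#'   states present) a `stateSubset` of that size must be supplied.
#' @param fusion Fusion group.
#' @param stateSubset Optional character vector of states to keep.
#' @param minPerState Minimum events required per state across the cohort;
#'   falling short raises an "insufficient data" error (the untestable grid
#'   cells are reported as NaN rows by [runExperimentGrid()] instead).
#' @return A [SensorVariant-class].
#' @export
buildDatasetVariant <- function(sessions, sampling = c("interpolate", "subsample"),
                                nStates, fusion = "IMU", stateSubset = NULL,
                                minPerState = 1L) {
  sampling <- match.arg(sampling)
  fusion <- match.arg(fusion, FUSIONS)
  stopIfNot(is.list(sessions) && length(sessions) >= 1L,
            "sessions must be a non-empty list")
  if (!all(vapply(sessions, function(s) s@normalized, logical(1))))
    warning("some sessions are not Z-normalized; variants are usually built ",
            "from znormalizeSession() output", call. = FALSE)
  allStates <- sort(unique(unlist(lapply(sessions, function(s) s@events$state))))
  vocab <- if (is.null(stateSubset)) allStates else sort(unique(stateSubset))
  stopIfNot(length(vocab) == nStates,
            sprintf("vocabulary size %d does not match nStates = %d",
                    length(vocab), nStates))

  chans <- fusionChannels(fusion)
  mats <- list(); labs <- character(); prov <- list()
  for (s in sessions) {
    ev <- s@events
    keep <- which(ev$state %in% vocab)
    for (e in keep) {
      al <- interpolateEvent(s, e, fusion)
      if (sampling == "interpolate") {
        mats[[length(mats) + 1L]] <- al@values
        labs <- c(labs, al@label)
        prov[[length(prov) + 1L]] <- data.frame(
          dogId = s@dogId, eventIndex = e, windowIndex = NA_integer_)
      } else {
        for (k in seq_len(N_WINDOWS) - 1L) {
          rows <- (k * WINDOW_LEN + 1L):((k + 1L) * WINDOW_LEN)
          mats[[length(mats) + 1L]] <- al@values[rows, , drop = FALSE]
          labs <- c(labs, al@label)
          prov[[length(prov) + 1L]] <- data.frame(
            dogId = s@dogId, eventIndex = e, windowIndex = k)
        }
      }
    }
  }
  stopIfNot(length(mats) > 0L, "no events matched the requested state subset")
  perState <- table(factor(labs, levels = vocab)) /
    if (sampling == "subsample") N_WINDOWS else 1
  if (any(perState < minPerState))
    stop("insufficient data: state(s) below minPerState events: ",
         paste(names(perState)[perState < minPerState], collapse = ", "),
         call. = FALSE)
  TT <- nrow(mats[[1]]); C <- length(chans); n <- length(mats)
  arr <- array(NA_real_, c(n, TT, C))
  for (i in seq_len(n)) arr[i, , ] <- mats[[i]]
  new("SensorVariant", sampling = sampling, nStates = as.integer(nStates),
      fusion = fusion, samples = arr, labels = labs, vocabulary = vocab,
      provenance = do.call(rbind, prov))
}

#' SplitVariant: train/test partition of a variant
#'
#' @slot variant The parent [SensorVariant-class].
#' @slot trainIdx,testIdx Sample indices.
#' @slot ratio Train fraction.
#' @slot seed Split seed.
#' @slot level `"event"` (all windows of one event stay together; leakage
#'   safe, the default) or `"window"` (windows split independently).
#' @export
setClass("SplitVariant", representation(
  variant = "SensorVariant", trainIdx = "integer", testIdx = "integer",
  ratio = "numeric", seed = "numeric", level = "character"))

setMethod("show", "SplitVariant", function(object) {
  cat(sprintf("SplitVariant (%s level): %d train / %d test (ratio %.2f)\n",
              object@level, length(object@trainIdx), length(object@testIdx),
              object@ratio))
})

#' @describeIn SplitVariant-class Training-side variant.
#' @param split A [SplitVariant-class].
#' @export
trainVariant <- function(split) variantSubset(split@variant, split@trainIdx)

#' @describeIn SplitVariant-class Test-side variant.
#' @export
testVariant <- function(split) variantSubset(split@variant, split@testIdx)

#' Stratified train/test split
#'
#' Splits a variant into train and test sides, stratified by label. At
#' `level = "event"` all windows of one event land on the same side (no
#' leakage between a window and its siblings); at `level = "window"` windows
#' are assigned independently. A label with fewer than 2 groups is assigned
#' wholly to train with a warning.
#'
#' @param variant A [SensorVariant-class].
#' @param ratio Train fraction in (0, 1); default 0.7.
#' @param seed Split seed.
#' @param level `"event"` or `"window"`.
#' @return A [SplitVariant-class].
#' @export
splitTrainTest <- function(variant, ratio = 0.7, seed = 1,
                           level = c("event", "window")) {
  level <- match.arg(level)
  stopIfNot(ratio > 0 && ratio < 1, "ratio must lie in (0, 1)")
  prov <- variant@provenance
  group <- if (level == "event")
    paste(prov$dogId, prov$eventIndex, sep = "#") else
    paste(prov$dogId, prov$eventIndex, prov$windowIndex, sep = "#")
  labs <- variant@labels
  groupLab <- tapply(labs, group, function(x) x[1])
  trainGroups <- withSeed(seed, {
    out <- character()
    for (lv in sort(unique(as.character(groupLab)))) {
      g <- names(groupLab)[groupLab == lv]
      if (length(g) < 2L) {
        warning("label '", lv, "' has fewer than 2 groups; assigned to train",
                call. = FALSE)
        out <- c(out, g)
      } else {
        nTr <- max(1L, min(length(g) - 1L, round(ratio * length(g))))
        out <- c(out, sample(g)[seq_len(nTr)])
      }
    }
    out
  })
  isTrain <- group %in% trainGroups
  new("SplitVariant", variant = variant,
      trainIdx = which(isTrain), testIdx = which(!isTrain),
      ratio = ratio, seed = as.numeric(seed), level = level)
}
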