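#' Median-distance heuristic for the RBF gamma
#'
#' `1 / median(||x_i - x_j||^2)` over (a subsample of) the rows, a standard
#' starting point for the kernel width on standardised data.
#'
#' @param X Sample matrix.
#' @param maxN Rows to subsample for the median (default 200).
#' @param seed Seed for the subsample.
#' @return A positive scalar.
#' @export
gammaHeuristic <- function(X, maxN = 200, seed = 1) {
  X <- as.matrix(X)
  idx <- if (nrow(X) > maxN)
    withSeed(seed, sample(nrow(X), maxN)) else seq_len(nrow(X))
  d2 <- dist(X[idx, , drop = FALSE])^2
  m <- median(d2)
  if (!is.finite(m) || m <= 0) 1 else 1 / m
}

#' Preliminary selection of the most distinguishable states
#'
#' Runs a fast KPCA + ridge model on the interpolated 50-state IMU variant
#' and keeps the `k` states with the highest test recall — the procedure used
#' to pick the reduced 10-state vocabulary from the full protocol.
#'
#' @param sessions Z-normalized sessions.
#' @param k States to keep (default 10).
#' @param trainCap,testCap Stratified sample caps keeping the preliminary fit
#'   fast (defaults 400/400).
#' @param alpha Ridge penalty.
#' @param seed Seed for split and caps.
#' @return Character vector of `k` state names.
#' @export
preliminaryStateSelection <- function(sessions, k = 10, trainCap = 400,
                                      testCap = 400, alpha = 1, seed = 1) {
  nStates <- length(unique(unlist(lapply(sessions, function(s) s@events$state))))
  variant <- buildDatasetVariant(sessions, "interpolate", nStates, "IMU")
  split <- splitTrainTest(variant, 0.7, seed = seed, level = "event")
  trX <- flattenSamples(trainVariant(split)); trY <- sampleLabels(trainVariant(split))
  teX <- flattenSamples(testVariant(split)); teY <- sampleLabels(testVariant(split))
  if (nrow(trX) > trainCap) {
    red <- reduceTrainingSet(trX, trY, trainCap / nrow(trX), seed = seed)
    trX <- red$X; trY <- red$labels
  }
  if (nrow(teX) > testCap) {
    red <- reduceTrainingSet(teX, teY, testCap / nrow(teX), seed = seed + 1)
    teX <- red$X; teY <- red$labels
  }
  km <- fitKPCA(trX, gammaHeuristic(trX), nComponents = 128)
  rmod <- fitRidge(km@trainProj, trY, alpha)
  pred <- predictKpcaRidge(km, rmod, teX)
  cm <- confusionCounts(teY, pred, variantVocabulary(variant))
  selectTopStates(cm, k)
}

#' Run the full experiment grid
#'
#' Enumerates the ten testable dataset variants — both samplings, 10- and
#' 50-state vocabularies and the three fusion groups, excluding the two
#' 50-state IMU-Audio-Env cells for which the 1 Hz environmental channels
#' cannot supply enough per-state data — and evaluates both classifiers on
#' each, returning one report row per (variant, model) pair. The two
#' excluded cells appear as explicit NaN rows. Failures inside a cell are
#' recorded as NaN rows rather than aborting the grid.
#'
#' @param sessions Z-normalized sessions (e.g. from [generateCohort()] +
#'   [znormalizeSession()]).
#' @param stateSubset Character vector of 10 states for the reduced
#'   vocabulary; default comes from [preliminaryStateSelection()].
#' @param lstmConfig Base [convLSTMConfig()] for all Conv-LSTM fits
#'   (`denseOut` is set per cell).
#' @param alpha Ridge penalty.
#' @param kpcaComponents Components retained by KPCA.
#' @param trainCap,testCap Optional stratified caps on the per-cell train and
#'   test sizes (NULL = no cap).
#' @param kpcaReduceSubsample Stratified reduction factor applied to KPCA
#'   training sets on the (much larger) subsample variants, mirroring the
#'   quarter/sixteenth downsampling the kernel eigendecomposition requires
#'   at scale (default 0.25).
#' @param ratio,level,seed Split settings (event-level by default,
#'   leakage-safe).
#' @return `data.frame` with columns `sampling`, `nStates`, `fusion`,
#'   `model`, `macroPrecision`, `macroRecall`, `macroF1`, `accuracy`,
#'   `nTrain`, `nTest`; confusion matrices of evaluated cells are attached
#'   as attribute `"confusions"`.
#' @export
runExperimentGrid <- function(sessions, stateSubset = NULL,
                              lstmConfig = convLSTMConfig(),
                              alpha = 1, kpcaComponents = 128,
                              trainCap = NULL, testCap = NULL,
                              kpcaReduceSubsample = 0.25,
                              ratio = 0.7, level = "event", seed = 1) {
  if (is.null(stateSubset))
    stateSubset <- preliminaryStateSelection(sessions, 10, seed = seed)
  grid <- expand.grid(sampling = c("interpolate", "subsample"),
                      nStates = c(10L, 50L),
                      fusion = FUSIONS, stringsAsFactors = FALSE)
  allStates <- sort(unique(unlist(lapply(sessions, function(s) s@events$state))))
  rows <- list(); confusions <- list()
  nanRow <- function(g, model) data.frame(
    sampling = g$sampling, nStates = g$nStates, fusion = g$fusion,
    model = model, macroPrecision = NaN, macroRecall = NaN, macroF1 = NaN,
    accuracy = NaN, nTrain = NA_integer_, nTest = NA_integer_)

  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    cellId <- paste(g$sampling, g$nStates, g$fusion, sep = "/")
    if (g$nStates == 50L && g$fusion == "IMU-Audio-Env") {
      rows <- c(rows, list(nanRow(g, "convlstm"), nanRow(g, "kpca")))
      next
    }
    res <- tryCatch({
      subset <- if (g$nStates == 10L) stateSubset else allStates
      variant <- buildDatasetVariant(sessions, g$sampling, g$nStates,
                                     g$fusion, stateSubset = subset)
      split <- splitTrainTest(variant, ratio, seed = seed, level = level)
      trV <- trainVariant(split); teV <- testVariant(split)
      trIdx <- seq_len(nSamples(trV)); teIdx <- seq_len(nSamples(teV))
      if (!is.null(trainCap) && nSamples(trV) > trainCap)
        trIdx <- withSeed(seed + r, stratifiedIndices(
          sampleLabels(trV), trainCap / nSamples(trV)))
      if (!is.null(testCap) && nSamples(teV) > testCap)
        teIdx <- withSeed(seed + r + 1000, stratifiedIndices(
          sampleLabels(teV), testCap / nSamples(teV)))
      trV <- variantSubset(trV, trIdx); teV <- variantSubset(teV, teIdx)
      vocab <- variantVocabulary(variant)
      cellRows <- list()

      # Conv-LSTM
      cfg <- lstmConfig; cfg$denseOut <- NULL
      cappedSplit <- new("SplitVariant",
                         variant = variant,
                         trainIdx = split@trainIdx[trIdx],
                         testIdx = split@testIdx[teIdx],
                         ratio = ratio, seed = as.numeric(seed), level = level)
      fit <- trainConvLSTM(cappedSplit, cfg)
      predL <- predictConvLSTM(fit$model, teV)
      cmL <- confusionCounts(sampleLabels(teV), predL, vocab)
      confusions[[paste0(cellId, "/convlstm")]] <- cmL
      cellRows$lstm <- data.frame(
        sampling = g$sampling, nStates = g$nStates, fusion = g$fusion,
        model = "convlstm", as.data.frame(macroReport(cmL)),
        nTrain = nSamples(trV), nTest = nSamples(teV))
      names(cellRows$lstm)[5:8] <- c("macroPrecision", "macroRecall",
                                     "macroF1", "accuracy")

      # KPCA + ridge
      trX <- flattenSamples(trV); trY <- sampleLabels(trV)
      if (g$sampling == "subsample" && kpcaReduceSubsample < 1) {
        red <- reduceTrainingSet(trX, trY, kpcaReduceSubsample, seed = seed + r)
        trX <- red$X; trY <- red$labels
      }
      km <- fitKPCA(trX, gammaHeuristic(trX), nComponents = kpcaComponents)
      rmod <- fitRidge(km@trainProj, trY, alpha)
      predK <- predictKpcaRidge(km, rmod, flattenSamples(teV))
      cmK <- confusionCounts(sampleLabels(teV), predK, vocab)
      confusions[[paste0(cellId, "/kpca")]] <- cmK
      cellRows$kpca <- data.frame(
        sampling = g$sampling, nStates = g$nStates, fusion = g$fusion,
        model = "kpca", as.data.frame(macroReport(cmK)),
        nTrain = nrow(trX), nTest = nSamples(teV))
      names(cellRows$kpca)[5:8] <- c("macroPrecision", "macroRecall",
                                     "macroF1", "accuracy")
      cellRows
    }, error = function(e) {
      warning("grid cell ", cellId, " failed: ", conditionMessage(e),
              call. = FALSE)
      list(lstm = nanRow(g, "convlstm"), kpca = nanRow(g, "kpca"))
    })
    rows <- c(rows, unname(res))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "stateSubset") <- stateSubset
  attr(out, "confusions") <- confusions
  out
}

#' Write grid results as a CSV report
#'
#' Columns mirror the macro precision / recall / F1 / accuracy layout of the
#' per-variant result tables.
#'
#' @param rows Output of [runExperimentGrid()].
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
exportReportCSV <- function(rows, path) {
  out <- data.frame(
    Dataset = paste(substr(rows$sampling, 1, 6), rows$nStates, rows$fusion),
    Model = rows$model,
    `Mac-Prec` = round(rows$macroPrecision, 3),
    `Mac-Recall` = round(rows$macroRecall, 3),
    `Mac-F1-Score` = round(rows$macroF1, 3),
    Acc = round(rows$accuracy, 3), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
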