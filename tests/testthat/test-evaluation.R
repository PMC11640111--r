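test_that("confusion counts match hand tallies", {
  cm <- confusionCounts(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(cm, matrix(c(1L, 0L, 1L, 1L), 2, 2,
                              dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sum(cm), 3)
  perfect <- confusionCounts(rep(c("A", "B"), 5), rep(c("A", "B"), 5),
                             c("A", "B"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusionCounts("A", "C", c("A", "B")), "outside vocabulary")
})

test_that("macro metrics match hand computation and the brute-force oracle", {
  expect_equal(unlist(macroReport(diag(5L, 2))), c(macroPrecision = 1,
               macroRecall = 1, macroF1 = 1, accuracy = 1))
  r <- macroReport(rbind(c(8L, 2L), c(3L, 7L)))
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$macroPrecision, (8 / 11 + 7 / 9) / 2, tolerance = 1e-12)
  expect_equal(r$macroRecall, 0.75)
  # a never-predicted class contributes 0 precision
  cm0 <- rbind(c(0L, 4L), c(0L, 6L))
  expect_equal(macroReport(cm0)$macroPrecision, (0 + 6 / 10) / 2)

  withr::with_seed(41, {
    for (i in 1:100) {
      K <- sample(2:8, 1)
      cm <- matrix(rpois(K * K, 3), K, K)
      if (sum(cm) == 0) cm[1, 1] <- 1
      expect_equal(macroReport(cm), bruteMacro(cm), tolerance = 1e-12)
    }
  })
})

test_that("prediction flow applies the null-state rule and diagonal tie-break", {
  nm <- c("A", "B", "C")
  cm <- rbind(c(9, 1, 0), c(0, 10, 0), c(4, 3, 3))
  dimnames(cm) <- list(nm, nm)
  fl <- predictionFlow(cm, theta = 0.3)
  expect_identical(fl$target, c("A", "B", "A"))
  expect_equal(fl$topShare, c(0.9, 1, 0.4))

  # even confusion over many states maps to null
  K <- 50
  cmU <- matrix(2L, K, K, dimnames = list(sprintf("s%02d", 1:K),
                                          sprintf("s%02d", 1:K)))
  flU <- predictionFlow(cmU, theta = 0.3)
  expect_true(all(is.na(flU$target)))

  # identity confusion maps every state to itself at any theta
  cmI <- diag(7L, 4); dimnames(cmI) <- list(nm4 <- paste0("t", 1:4), nm4)
  expect_identical(predictionFlow(cmI, theta = 1)$target, nm4)

  # theta -> 0+ never yields null; theta = 1 spares only perfect rows
  cm2 <- rbind(c(5, 5), c(0, 4)); dimnames(cm2) <- list(c("A","B"), c("A","B"))
  expect_false(anyNA(predictionFlow(cm2, theta = 1e-9)$target))
  fl1 <- predictionFlow(cm2, theta = 1)
  expect_true(is.na(fl1$target[1]))    # 50% top share < 1
  expect_identical(fl1$target[2], "B")
  # tie at 50/50 broke toward the diagonal
  expect_identical(predictionFlow(cm2, theta = 0.3)$target[1], "A")
})

test_that("aggregate recommendations group shared targets and list null states", {
  nm <- paste0("q", 1:4)
  cmI <- diag(3L, 4); dimnames(cmI) <- list(nm, nm)
  rec <- aggregateRecommendations(predictionFlow(cmI, 0.3))
  expect_length(rec$groups, 4)
  expect_true(all(lengths(rec$groups) == 1))
  expect_length(rec$nullStates, 0)
  expect_equal(unname(rec$counts["nUniquelyIdentified"]), 4)

  # four states all flowing into E form one aggregate of five
  nm5 <- c("A", "B", "C", "D", "E")
  cm5 <- matrix(0L, 5, 5, dimnames = list(nm5, nm5))
  cm5[, "E"] <- 10L; cm5["E", "E"] <- 10L
  rec5 <- aggregateRecommendations(predictionFlow(cm5, 0.3))
  expect_length(rec5$groups, 1)
  expect_setequal(rec5$groups[["E"]], nm5)

  # null states are accounted against the total
  cmN <- diag(10L, 6)
  cmN[5, ] <- 1L; cmN[6, ] <- 1L   # two evenly-confused states
  dimnames(cmN) <- list(paste0("n", 1:6), paste0("n", 1:6))
  recN <- aggregateRecommendations(predictionFlow(cmN, 0.3))
  expect_length(recN$nullStates, 2)
  expect_equal(sum(lengths(recN$groups)) + length(recN$nullStates), 6)
})

test_that("sankey export pairs every true state with one target", {
  nm <- c("A", "B", "C")
  cm <- rbind(c(9, 1, 0), c(0, 10, 0), c(1, 1, 1))
  dimnames(cm) <- list(nm, nm)
  fl <- predictionFlow(cm, theta = 0.5)
  sk <- sankeyData(fl, cm)
  expect_equal(nrow(sk$links), 3)
  expect_identical(sk$links$target[3], "pred:null")
  path <- tempfile(fileext = ".json")
  exportSankeyJSON(fl, cm, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed$links, 3)
})

test_that("the experiment grid enumerates testable variants and flags the rest", {
  cfg <- cohortConfig(nDogs = 3, durationRange = c(1.5, 2.5), masterSeed = 6)
  coh <- lapply(generateCohort(cfg), function(s) znormalizeSession(s)$session)
  sub <- c("Idle", "Vacuum on-On leash", "Noise can shake", "Umbrella opens",
           "Fan passes", "Explore-Enters Space", "Trot on leash",
           "Sees Unusual Person", "Exam complete", "Recall")
  lcfg <- convLSTMConfig(convWidth = 8, nConvLayers = 2, lstmHidden = 8,
                         epochs = 2, batchSize = 32, seed = 2,
                         valFraction = 0, patience = Inf)
  # stratified caps on 50-state cells legitimately empty some classes in the
  # KPCA reduction, which warns; that is the intended small-scale behaviour
  rows <- suppressWarnings(
    runExperimentGrid(coh, stateSubset = sub, lstmConfig = lcfg,
                      trainCap = 150, testCap = 150,
                      kpcaComponents = 32, seed = 3))
  expect_equal(nrow(rows), 24)           # 20 evaluated + 4 explicit NaN rows
  expect_equal(sum(!is.nan(rows$accuracy)), 20)
  nanRows <- rows[is.nan(rows$accuracy), ]
  expect_true(all(nanRows$nStates == 50 & nanRows$fusion == "IMU-Audio-Env"))
  ok <- rows[!is.nan(rows$accuracy), ]
  for (col in c("macroPrecision", "macroRecall", "macroF1", "accuracy"))
    expect_true(all(ok[[col]] >= 0 & ok[[col]] <= 1))
  expect_setequal(unique(rows$model), c("convlstm", "kpca"))
  # confusion matrices stored for evaluated cells
  expect_length(attr(rows, "confusions"), 20)
  # CSV export round-trips the table shape
  path <- tempfile(fileext = ".csv")
  exportReportCSV(rows, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 24)
  expect_true(all(c("Mac-Prec", "Mac-Recall", "Mac-F1-Score", "Acc")
                  %in% names(back)))
})
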