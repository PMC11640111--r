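#' Confusion matrix of counts
#'
#' @param truth True labels.
#' @param predicted Predicted labels, same length.
#' @param vocabulary Ordered label list; every label must belong to it.
#' @return `K x K` integer matrix, rows = true, columns = predicted, with the
#'   vocabulary as dimnames.
#' @examples
#' confusionCounts(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' @export
confusionCounts <- function(truth, predicted, vocabulary) {
  stopIfNot(length(truth) == length(predicted),
            "truth and predicted must have the same length")
  bad <- setdiff(unique(c(truth, predicted)), vocabulary)
  stopIfNot(length(bad) == 0L,
            paste("labels outside vocabulary:", paste(bad, collapse = ", ")))
  tt <- factor(as.character(truth), levels = vocabulary)
  pp <- factor(as.character(predicted), levels = vocabulary)
  m <- table(tt, pp)
  matrix(as.integer(m), nrow(m), ncol(m),
         dimnames = list(vocabulary, vocabulary))
}

#' Macro-averaged classification report
#'
#' Per-class precision is the diagonal count over the column sum (0 for a
#' class never predicted), recall the diagonal over the row sum (0 for a
#' class never occurring), and F1 their harmonic mean (0 when both are 0).
#' Macro values are unweighted class means; accuracy is trace over total.
#' Macro-F1 is the mean of per-class F1 values, not the F1 of macro
#' precision/recall.
#'
#' @param cm Square confusion matrix of counts (rows = true).
#' @return List with `macroPrecision`, `macroRecall`, `macroF1`, `accuracy`.
#' @examples
#' macroReport(confusionCounts(c("A", "A", "B", "B"),
#'                             c("A", "B", "B", "B"), c("A", "B")))
#' @export
macroReport <- function(cm) {
  stopIfNot(is.matrix(cm) && nrow(cm) == ncol(cm) && nrow(cm) >= 2,
            "cm must be a square matrix with K >= 2")
  total <- sum(cm)
  stopIfNot(total > 0, "empty confusion matrix")
  d <- diag(cm); rs <- rowSums(cm); cs <- colSums(cm)
  prec <- ifelse(cs > 0, d / cs, 0)
  rec <- ifelse(rs > 0, d / rs, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(macroPrecision = mean(prec), macroRecall = mean(rec),
       macroF1 = mean(f1), accuracy = sum(d) / total)
}

#' Most-common-prediction state flow with null-state rule
#'
#' For each true state the target is the most common predicted state,
#' provided that prediction's share of the row is at least `theta`; a state
#' confused evenly across many others (top share below `theta`) maps to the
#' null state. Ties are broken toward the diagonal, then lexicographically.
#'
#' @param cm Square confusion matrix of counts (rows = true).
#' @param theta Evenness threshold in (0, 1]; default 0.30.
#' @return `data.frame` with columns `state`, `target` (`NA` for null) and
#'   `topShare`, with `theta` attached as an attribute.
#' @export
predictionFlow <- function(cm, theta = 0.30) {
  stopIfNot(is.matrix(cm) && nrow(cm) == ncol(cm), "cm must be square")
  stopIfNot(theta > 0 && theta <= 1, "theta must lie in (0, 1]")
  states <- rownames(cm)
  out <- data.frame(state = states, target = NA_character_,
                    topShare = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cm))) {
    row <- cm[i, ]
    tot <- sum(row)
    if (tot == 0) {
      warning("state '", states[i], "' never occurs; mapped to null",
              call. = FALSE)
      out$topShare[i] <- 0
      next
    }
    best <- max(row)
    cand <- which(row == best)
    j <- if (i %in% cand) i else cand[order(colnames(cm)[cand])][1]
    share <- best / tot
    out$topShare[i] <- share
    if (share >= theta) out$target[i] <- colnames(cm)[j]
  }
  attr(out, "theta") <- theta
  out
}

#' Aggregate-state recommendations from a state flow map
#'
#' States sharing a flow target form one aggregate group (together with the
#' target itself); stand-alone null-mapped states are listed for removal.
#' Uniquely identified states are singleton groups that map to themselves.
#' Group sizes plus null states partition the full state list.
#'
#' @param flow Output of [predictionFlow()].
#' @return List with `groups` (named list of character vectors, keyed by
#'   target), `nullStates`, and `counts` (`nGroups`, `nNull`,
#'   `nUniquelyIdentified`).
#' @export
aggregateRecommendations <- function(flow) {
  stopIfNot(is.data.frame(flow) && all(c("state", "target") %in% names(flow)),
            "flow must be a predictionFlow() data.frame")
  nullStates <- flow$state[is.na(flow$target)]
  mapped <- flow[!is.na(flow$target), , drop = FALSE]
  groups <- list()
  for (tg in sort(unique(mapped$target))) {
    members <- sort(unique(c(tg, mapped$state[mapped$target == tg])))
    groups[[tg]] <- members
  }
  # a target that is itself null-mapped still anchors its group; drop states
  # counted twice (a state can only belong to the group of its own target)
  own <- setNames(mapped$target, mapped$state)
  for (tg in names(groups)) {
    keep <- vapply(groups[[tg]], function(s) {
      is.na(own[s]) || identical(unname(own[s]), tg) || s == tg
    }, logical(1))
    groups[[tg]] <- groups[[tg]][keep]
  }
  uniq <- sum(vapply(names(groups), function(tg) {
    length(groups[[tg]]) == 1L && groups[[tg]] == tg
  }, logical(1)))
  list(groups = groups,
       nullStates = nullStates,
       counts = c(nGroups = length(groups), nNull = length(nullStates),
                  nUniquelyIdentified = uniq))
}

#' Sankey-style node/link export of a state flow map
#'
#' @param flow Output of [predictionFlow()].
#' @param cm The confusion matrix the flow was computed from (for link
#'   weights).
#' @return List with `nodes` (data.frame `name`, `side`) and `links`
#'   (data.frame `source`, `target`, `weight`), consumable by standard
#'   plotting tools.
#' @export
sankeyData <- function(flow, cm) {
  src <- flow$state
  tgt <- ifelse(is.na(flow$target), "null", flow$target)
  w <- vapply(seq_along(src), function(i) {
    row <- cm[src[i], ]
    if (is.na(flow$target[i])) sum(row) else row[[flow$target[i]]]
  }, numeric(1))
  nodes <- data.frame(
    name = c(paste0("true:", src), unique(paste0("pred:", tgt))),
    side = c(rep("true", length(src)),
             rep("pred", length(unique(tgt)))),
    stringsAsFactors = FALSE)
  links <- data.frame(source = paste0("true:", src),
                      target = paste0("pred:", tgt),
                      weight = w, stringsAsFactors = FALSE)
  list(nodes = nodes, links = links)
}

#' Write a Sankey export as JSON
#'
#' @param flow,cm As in [sankeyData()].
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
exportSankeyJSON <- function(flow, cm, path) {
  jsonlite::write_json(sankeyData(flow, cm), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
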