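#' Export a session to a directory of CSV files
#'
#' Writes one CSV per modality (`time_s, ch1..chC`) plus `events.csv`
#' (`state,start_s,end_s`). Numbers are written with 15 significant digits so
#' a round trip preserves values to better than 1e-9, and the formatting is
#' deterministic: re-exporting an identical session is byte-identical.
#'
#' @param session A [CollarSession-class].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the vector of files written (7 for a full session).
#' @seealso [importSession()]
#' @export
exportSession <- function(session, directory) {
  stopIfNot(is(session, "CollarSession"), "session must be a CollarSession")
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", directory, call. = FALSE)
  fmt <- function(x) sprintf("%.15g", x)
  files <- character()
  for (m in MODALITIES) {
    s <- session@streams[[m]]
    path <- file.path(directory, paste0(m, ".csv"))
    C <- ncol(s@values)
    header <- paste(c("time_s", paste0("ch", seq_len(C))), collapse = ",")
    body <- fmt(s@timestamps)
    for (j in seq_len(C)) body <- paste(body, fmt(s@values[, j]), sep = ",")
    ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("failed to write ", path, ": ", ok, call. = FALSE)
    files <- c(files, path)
  }
  ev <- session@events
  evPath <- file.path(directory, "events.csv")
  writeLines(c("state,start_s,end_s",
               paste(ev$state, fmt(ev$start_s), fmt(ev$end_s), sep = ",")),
             evPath)
  invisible(c(files, evPath))
}

#' Import a session from the CSV export layout
#'
#' Inverse of [exportSession()]: `importSession(exportSession(s))` reproduces
#' `s` up to 1e-9 on values and exactly on labels and (rounded) times. Missing
#' modality files and non-monotone timestamps are format errors; malformed
#' rows (missing fields) raise an error rather than being silently dropped.
#'
#' @param directory Directory holding the export layout.
#' @param strict If `TRUE`, out-of-order events on disk are an error; if
#'   `FALSE` (default) they are re-sorted by start time.
#' @return A [CollarSession-class] with `seed = NA` and `dogId` taken from the
#'   directory name.
#' @export
importSession <- function(directory, strict = FALSE) {
  stopIfNot(dir.exists(directory), paste("no such directory:", directory))
  streams <- list()
  for (m in MODALITIES) {
    path <- file.path(directory, paste0(m, ".csv"))
    if (!file.exists(path))
      stop("missing modality file for '", m, "': ", path, call. = FALSE)
    df <- read.csv(path, check.names = FALSE)
    C <- MODALITY_CHANNELS[[m]]
    if (ncol(df) != C + 1L || anyNA(df))
      stop("corrupt file for modality '", m,
           "': row/column count mismatch or missing values", call. = FALSE)
    tt <- df[[1]]
    if (length(tt) > 1L && any(diff(tt) <= 0))
      stop("non-monotone timestamps in modality '", m, "'", call. = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    dimnames(vals) <- list(NULL, switch(m, imu = c("x", "y", "z"),
                                        audio = "db", m))
    streams[[m]] <- new("SensorStream", modality = m,
                        rateHz = MODALITY_RATE[[m]],
                        timestamps = as.numeric(tt),
                        values = vals)
  }
  evPath <- file.path(directory, "events.csv")
  if (!file.exists(evPath)) stop("missing events.csv", call. = FALSE)
  ev <- read.csv(evPath, stringsAsFactors = FALSE)
  if (anyNA(ev)) stop("corrupt events.csv: missing values", call. = FALSE)
  if (is.unsorted(ev$start_s, strictly = FALSE)) {
    if (strict) stop("events out of order on disk (strict mode)", call. = FALSE)
    ev <- ev[order(ev$start_s), , drop = FALSE]
    rownames(ev) <- NULL
  }
  durationS <- max(vapply(streams, function(s) {
    if (length(s@timestamps)) max(s@timestamps) + 1 / s@rateHz else 0
  }, numeric(1)), ev$end_s)
  new("CollarSession", dogId = basename(directory), seed = NA_real_,
      streams = streams, events = ev, durationS = durationS,
      normalized = FALSE)
}
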