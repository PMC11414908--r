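#' Read event tables
#'
#' Reads a delimited event table (columns `time_s`, `kind`, `unit_id` and
#' optionally `trial_id`; times in seconds) and returns one validated
#' \linkS4class{EventSeries} per (kind, unit, trial) combination, with times
#' converted to milliseconds.  The delimiter is auto-detected (tab or comma)
#' unless given.
#'
#' @param path file path.
#' @param delim field delimiter, `NULL` for auto-detection.
#' @return Named list of \linkS4class{EventSeries}.  Malformed rows and
#'   non-monotone series abort with an error naming the offending lines.
#' @seealso [writeEvents()]
#' @export
readEvents <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.delim(path, sep = delim, stringsAsFactors = FALSE)
  need <- c("time_s", "kind", "unit_id")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!nrow(df)) return(list())
  if (!"trial_id" %in% names(df)) df$trial_id <- NA
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))))
  if (length(bad))
    stop("malformed time_s values at line(s) ",
         paste(bad + 1L, collapse = ", "))   # +1: header line
  df$time_s <- as.numeric(df$time_s)
  key <- paste(df$kind, df$unit_id, df$trial_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    t <- df$time_s[idx]
    nonMono <- which(diff(t) <= 0)
    if (length(nonMono))
      stop("non-monotone timestamps for series '", df$unit_id[idx[1L]],
           "' at row index(es) ",
           paste(idx[nonMono + 1L] + 1L, collapse = ", "))
    EventSeries(t * 1000, kind = df$kind[idx[1L]],
                unitId = as.character(df$unit_id[idx[1L]]),
                trialId = as.character(df$trial_id[idx[1L]]))
  })
  names(out) <- vapply(strsplit(names(out), "\r"), function(p)
    paste(p[1L], p[2L], sep = ":"), "")
  out
}

#' Write event tables
#'
#' Writes one or more \linkS4class{EventSeries} as a tab-separated event
#' table with columns `time_s`, `kind`, `unit_id`, `trial_id` (times in
#' seconds).
#'
#' @param series an \linkS4class{EventSeries} or a list of them.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEvents <- function(series, path) {
  if (is(series, "EventSeries")) series <- list(series)
  rows <- lapply(series, function(s)
    data.frame(time_s = eventTimes(s) / 1000, kind = eventKind(s),
               unit_id = s@unitId, trial_id = s@trialId))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(time_s = numeric(0), kind = character(0),
                     unit_id = character(0), trial_id = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove spikes inside the EOD blanking window
#'
#' The EOD causes a large electrical artifact, so activity in a window
#' around every EOD (default \[-2.5, +2.5\] ms, closed) is removed before
#' any analysis.  A spike is retained only if its latency to *every* EOD
#' lies outside the window.
#'
#' @param spikes,eods \linkS4class{EventSeries} objects.
#' @param window numeric `(lo, hi)` in ms, `lo < hi`.
#' @return The blanked spike \linkS4class{EventSeries} (order preserved).
#'   With an empty EOD train the input is returned unchanged.
#' @examples
#' sp <- EventSeries(c(1, 10, 47), "spike")
#' ed <- EventSeries(c(0, 44.5), "EOD")
#' eventTimes(applyBlanking(sp, ed))   # spikes at 1 and 47 are removed
#' @export
applyBlanking <- function(spikes, eods, window = c(-2.5, 2.5)) {
  stopifnot(is(spikes, "EventSeries"), is(eods, "EventSeries"))
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be (lo, hi) with lo < hi")
  st <- eventTimes(spikes)
  et <- eventTimes(eods)
  if (!length(st) || !length(et)) return(spikes)
  # a spike s is blanked iff some EOD e satisfies lo <= s - e <= hi,
  # i.e. some EOD lies in [s - hi, s - lo]
  lo <- findInterval(st - window[2L], et, left.open = TRUE)
  hi <- findInterval(st - window[1L], et)
  keep <- hi == lo                      # no EOD inside the closed window
  initialize(spikes, times = st[keep])
}

#' Minimum-data filter for unit inclusion
#'
#' A unit enters the baseline analyses only if its recording holds at least
#' `minEods` EODs and its (blanked) spike train at least `minSpikes` spikes;
#' both thresholds are inclusive.
#'
#' @param units named list of units, each with `eods` and `spikes`
#'   \linkS4class{EventSeries} elements (spike counts are taken as given,
#'   i.e. post-blanking).
#' @param minEods,minSpikes inclusive thresholds (defaults 500 and 100).
#' @return Character vector of retained unit names.
#' @examples
#' ed <- generateEODTrain(nEods = 600, seed = 1)
#' u <- list(a = list(eods = ed,
#'                    spikes = EventSeries(seq(10, 5000, by = 40), "spike")))
#' minimumDataFilter(u)
#' @export
minimumDataFilter <- function(units, minEods = 500, minSpikes = 100) {
  ok <- vapply(units, function(u)
    nEvents(u$eods) >= minEods && nEvents(u$spikes) >= minSpikes, logical(1))
  names(units)[ok]
}
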