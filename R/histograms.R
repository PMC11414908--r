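## Pair-count core: counts, in 1 ms bins centered on integer latencies,
## every (spike, EOD) latency falling inside `window`.  A spike may
## contribute to the windows of several EODs (sliding cross-correlation
## construction).
.pairCounts <- function(st, et, window, binWidth = 1) {
  # bin k (center k * binWidth) covers [k - 1/2, k + 1/2) * binWidth; keep
  # every bin whose coverage intersects the half-open window [lo, hi)
  kmin <- ceiling(window[1L] / binWidth - 0.5 + 1e-9)
  kmax <- floor(window[2L] / binWidth + 0.5 - 1e-9)
  centers <- seq(kmin, kmax) * binWidth
  counts <- integer(length(centers))
  if (length(st)) {
    for (e in et) {
      i1 <- findInterval(e + window[1L], st, left.open = TRUE)
      i2 <- findInterval(e + window[2L] - 1e-12, st)
      if (i2 > i1) {
        lat <- st[(i1 + 1L):i2] - e
        b <- floor(lat / binWidth + 0.5) - kmin + 1L
        ok <- b >= 1L & b <= length(centers)
        if (any(ok))
          counts <- counts + tabulate(b[ok], nbins = length(centers))
      }
    }
  }
  list(centers = centers, counts = counts)
}

.blankedBinIdx <- function(centers, blank = c(-2.5, 2.5), binWidth = 1) {
  which(centers - binWidth / 2 >= blank[1L] & centers + binWidth / 2 <= blank[2L])
}

#' Cross-correlation histogram of spikes relative to the EOD
#'
#' For every EOD of the recording, the latencies of all spikes in the
#' analysis window (default 200 ms before to 300 ms after) are accumulated
#' into 1 ms bins centered on integer millisecond latencies (bin zero
#' centered on the EOD).  Values are expressed in percent per EOD: the
#' summed count per bin divided by the number of EODs, times 100.  Bins
#' lying inside the blanking window are flagged.
#'
#' @param spikes,eods \linkS4class{EventSeries}; blanking is assumed to have
#'   been applied to `spikes` already.
#' @param window analysis window `(lo, hi)` in ms relative to the EOD.
#' @param binWidth bin width in ms (default 1).
#' @param blank blanking window used to flag artifact bins.
#' @return A \linkS4class{PeriEODHistogram} in `percent_per_eod`
#'   normalization.
#' @examples
#' ed <- EventSeries(0, "EOD")
#' sp <- EventSeries(c(10.2, 10.7), "spike")
#' h <- crosscorrHistogram(sp, ed)
#' histValues(h)[binCenters(h) == 10]   # two spikes / one EOD x 100 = 200
#' @export
crosscorrHistogram <- function(spikes, eods, window = c(-200, 300),
                               binWidth = 1, blank = c(-2.5, 2.5)) {
  stopifnot(is(spikes, "EventSeries"), is(eods, "EventSeries"))
  if (nEvents(eods) < 1L) stop("EOD series is empty (no reference events)")
  pc <- .pairCounts(eventTimes(spikes), eventTimes(eods), window, binWidth)
  new("PeriEODHistogram",
      binCenters = pc$centers,
      values = 100 * pc$counts / nEvents(eods),
      normalization = "percent_per_eod",
      window = as.numeric(window),
      nEODs = nEvents(eods), nSpikes = nEvents(spikes),
      blankedBins = as.integer(.blankedBinIdx(pc$centers, blank, binWidth)))
}

#' Spike-count-normalized post-EOD histogram
#'
#' The 2.5--40 ms slice of the cross-correlation histogram, normalized to
#' the total number of spikes in the window (a probability vector over 38
#' one-millisecond bins, centers 3..40 ms).  This normalization makes the
#' histogram independent of both the EOD count and the firing rate, so it
#' isolates the spike-timing pattern used for unit classification.
#'
#' @param spikes,eods \linkS4class{EventSeries} (blanked spikes).
#' @param window analysis window, default `c(2.5, 40)` ms (half-open at 40).
#' @param binWidth bin width in ms.
#' @return A \linkS4class{PeriEODHistogram} in `unit_sum` normalization, or
#'   `NULL` when no spike falls in the window (the unit is then excluded
#'   upstream).
#' @examples
#' ed <- EventSeries(c(0, 44), "EOD")
#' sp <- EventSeries(c(10.1, 10.4, 54.2), "spike")
#' sum(histValues(postEODHistogram(sp, ed)))
#' @export
postEODHistogram <- function(spikes, eods, window = c(2.5, 40), binWidth = 1) {
  stopifnot(is(spikes, "EventSeries"), is(eods, "EventSeries"))
  if (nEvents(eods) < 1L) stop("EOD series is empty (no reference events)")
  pc <- .pairCounts(eventTimes(spikes), eventTimes(eods), window, binWidth)
  tot <- sum(pc$counts)
  if (tot == 0L) return(NULL)
  new("PeriEODHistogram",
      binCenters = pc$centers,
      values = pc$counts / tot,
      normalization = "unit_sum",
      window = as.numeric(window),
      nEODs = nEvents(eods), nSpikes = as.integer(tot),
      blankedBins = integer(0))
}

#' Percentile profiles of peri-EOD histograms across units
#'
#' Per-bin percentile curves (default 20/50/80) of a collection of
#' histograms over a common window; these are the representative profiles
#' used to portray each unit cluster.
#'
#' @param histograms list of \linkS4class{PeriEODHistogram} with identical
#'   binning.
#' @param percentiles percentile levels in (0, 100).
#' @param window restrict to bins with centers inside `(lo, hi)` (default
#'   `c(-15, 40)` ms).
#' @return A matrix (bins x percentiles) with bin centers as rownames and an
#'   attribute `"centers"`.
#' @export
periEODProfile <- function(histograms, percentiles = c(20, 50, 80),
                           window = c(-15, 40)) {
  if (!length(histograms)) stop("need at least one histogram")
  ctr <- binCenters(histograms[[1L]])
  same <- vapply(histograms, function(h)
    length(binCenters(h)) == length(ctr) && all(binCenters(h) == ctr),
    logical(1))
  if (!all(same)) stop("histograms must share a common binning")
  keep <- ctr >= window[1L] & ctr <= window[2L]
  vals <- vapply(histograms, function(h) histValues(h)[keep],
                 numeric(sum(keep)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = sum(keep))
  out <- t(apply(vals, 1L, quantile, probs = percentiles / 100, names = FALSE))
  dimnames(out) <- list(ctr[keep], paste0("p", percentiles))
  attr(out, "centers") <- ctr[keep]
  out
}

#' Write a histogram as TSV with a JSON metadata sidecar
#'
#' @param hist a \linkS4class{PeriEODHistogram}.
#' @param path output TSV path; metadata goes to `<path>.meta.json`.
#' @return invisibly, the path.
#' @export
writeHistogram <- function(hist, path) {
  write.table(data.frame(bin_center_ms = binCenters(hist),
                         value = histValues(hist)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(normalization = histNormalization(hist),
               window = hist@window, n_eods = nEODs(hist),
               n_spikes = nSpikes(hist),
               blanked_bins = binCenters(hist)[blankedBins(hist)])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
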