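#' EventSeries: a monotone train of event timestamps
#'
#' Container for a single point process: either the EOD train of a recording
#' or the spike train of one sorted unit.  Times are stored in milliseconds
#' from the start of the recording; on-disk event tables use seconds (see
#' [readEvents()]).
#'
#' @slot times numeric, strictly increasing, non-negative timestamps (ms).
#' @slot kind `"EOD"` or `"spike"`.
#' @slot unitId unit label (`NA` for EOD trains).
#' @slot trialId optional trial label.
#'
#' @seealso [EventSeries()], [applyBlanking()], [readEvents()]
#' @export
setClass("EventSeries",
  representation(times = "numeric", kind = "character",
                 unitId = "character", trialId = "character"),
  prototype(times = numeric(0), kind = "spike",
            unitId = NA_character_, trialId = NA_character_))

setValidity("EventSeries", function(object) {
  msg <- character(0)
  if (length(object@kind) != 1L || !object@kind %in% c("EOD", "spike"))
    msg <- c(msg, "'kind' must be \"EOD\" or \"spike\"")
  t <- object@times
  if (anyNA(t))
    msg <- c(msg, "timestamps must be finite")
  else {
    if (length(t) && min(t) < 0)
      msg <- c(msg, "timestamps must be non-negative")
    if (is.unsorted(t, strictly = TRUE))
      msg <- c(msg, "timestamps must be strictly increasing (no duplicates)")
  }
  if (length(msg)) msg else TRUE
})

#' Create an EventSeries
#'
#' @param times event times in milliseconds, strictly increasing.
#' @param kind `"EOD"` or `"spike"`.
#' @param unitId,trialId optional labels.
#' @return An \linkS4class{EventSeries} object.
#' @examples
#' es <- EventSeries(c(10, 25.2, 60), kind = "spike", unitId = "u1")
#' nEvents(es)
#' @export
EventSeries <- function(times, kind = c("spike", "EOD"),
                        unitId = NA_character_, trialId = NA_character_) {
  kind <- match.arg(kind)
  new("EventSeries", times = as.numeric(times), kind = kind,
      unitId = as.character(unitId), trialId = as.character(trialId))
}

#' @rdname accessors
#' @export
setMethod("eventTimes", "EventSeries", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("eventKind", "EventSeries", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("unitLabel", "EventSeries", function(x) x@unitId)

#' @rdname accessors
#' @export
setMethod("nEvents", "EventSeries", function(x) length(x@times))

setMethod("show", "EventSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("EventSeries (%s) with %d events", object@kind, n))
  if (!is.na(object@unitId)) cat(sprintf(", unit %s", object@unitId))
  if (n) cat(sprintf(", span %.1f-%.1f ms", object@times[1L], object@times[n]))
  cat("\n")
})

#' PeriEODHistogram: binned spike-latency distribution relative to the EOD
#'
#' Latency histogram of spikes relative to EOD times, in 1 ms bins centered
#' on integer-millisecond latencies (bin k covers \[k - 0.5, k + 0.5) ms; bin
#' zero is centered on the EOD).  Two normalizations exist:
#' `"percent_per_eod"` (spikes per bin across all EODs, divided by the number
#' of EODs, times 100 -- the cross-correlation convention) and `"unit_sum"`
#' (probability vector over the analysis window -- the post-EOD convention
#' used for classification).
#'
#' @slot binCenters bin centers (ms relative to the EOD).
#' @slot values per-bin values (percent per EOD, or probabilities).
#' @slot normalization `"percent_per_eod"` or `"unit_sum"`.
#' @slot window analysis window (lo, hi) in ms.
#' @slot nEODs number of reference EODs.
#' @slot nSpikes number of spikes contributing to the histogram.
#' @slot blankedBins indices of bins lying inside the EOD blanking window.
#' @seealso [crosscorrHistogram()], [postEODHistogram()]
#' @export
setClass("PeriEODHistogram",
  representation(binCenters = "numeric", values = "numeric",
                 normalization = "character", window = "numeric",
                 nEODs = "integer", nSpikes = "integer",
                 blankedBins = "integer"))

setValidity("PeriEODHistogram", function(object) {
  msg <- character(0)
  if (length(object@binCenters) != length(object@values))
    msg <- c(msg, "binCenters and values must have equal length")
  if (any(object@values < 0))
    msg <- c(msg, "histogram values must be non-negative")
  if (!object@normalization %in% c("percent_per_eod", "unit_sum"))
    msg <- c(msg, "unknown normalization")
  if (object@normalization == "unit_sum" && object@nSpikes > 0L &&
      abs(sum(object@values) - 1) > 1e-9)
    msg <- c(msg, "unit_sum histogram must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("binCenters", "PeriEODHistogram", function(x) x@binCenters)

#' @rdname accessors
#' @export
setMethod("histValues", "PeriEODHistogram", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("histNormalization", "PeriEODHistogram", function(x) x@normalization)

#' @rdname accessors
#' @export
setMethod("nEODs", "PeriEODHistogram", function(x) x@nEODs)

#' @rdname accessors
#' @export
setMethod("nSpikes", "PeriEODHistogram", function(x) x@nSpikes)

#' @rdname accessors
#' @export
setMethod("blankedBins", "PeriEODHistogram", function(x) x@blankedBins)

setMethod("show", "PeriEODHistogram", function(object) {
  cat(sprintf("PeriEODHistogram [%g, %g] ms, %d bins, %s\n",
              object@window[1L], object@window[2L],
              length(object@values), object@normalization))
  cat(sprintf("  %d EODs, %d spikes, %d blanked bins\n",
              object@nEODs, object@nSpikes, length(object@blankedBins)))
})

#' Plot a peri-EOD histogram
#'
#' @param x a \linkS4class{PeriEODHistogram}.
#' @param y ignored.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
setMethod("plot", signature(x = "PeriEODHistogram", y = "missing"),
  function(x, y, ...) {
    ylab <- if (x@normalization == "percent_per_eod")
      "spikes per EOD (%)" else "relative frequency"
    mp <- barplot(x@values, names.arg = x@binCenters, space = 0, border = NA,
                  xlab = "latency to EOD (ms)", ylab = ylab, ...)
    invisible(mp)
  })

#' OrdinalAlignment: spike latencies indexed by ordinal EOD around a step
#'
#' For step-stimulation experiments, every trial is re-indexed relative to
#' the stimulus step: EOD_0 is the first EOD emitted at or after the step
#' time, and ordinals run from -nPre to +nPost.  Each slot of the alignment
#' holds the spike latencies (ms, measured to the preceding EOD) falling in
#' the inter-EOD interval that follows the given ordinal EOD.
#'
#' @slot ordinals integer ordinal indices (e.g. -25:25).
#' @slot latencies list (one element per trial) of lists of latency vectors,
#'   one vector per ordinal.
#' @slot counts matrix trials x ordinals of spike counts.
#' @slot unitId unit label.
#' @slot droppedTrials indices of steps dropped for insufficient flanking EODs.
#' @seealso [alignOrdinal()], [countsPerOrdinal()], [triadDistributions()]
#' @export
setClass("OrdinalAlignment",
  representation(ordinals = "integer", latencies = "list",
                 counts = "matrix", unitId = "character",
                 droppedTrials = "integer"))

setValidity("OrdinalAlignment", function(object) {
  msg <- character(0)
  if (ncol(object@counts) != length(object@ordinals))
    msg <- c(msg, "counts must have one column per ordinal")
  if (length(object@latencies) != nrow(object@counts))
    msg <- c(msg, "latencies must have one element per trial")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("ordinalIndex", "OrdinalAlignment", function(x) x@ordinals)

#' @rdname accessors
#' @export
setMethod("ordinalCounts", "OrdinalAlignment", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("ordinalLatencies", "OrdinalAlignment", function(x) x@latencies)

setMethod("show", "OrdinalAlignment", function(object) {
  cat(sprintf("OrdinalAlignment: %d trials, ordinals %d..%d, %d spikes\n",
              nrow(object@counts), min(object@ordinals), max(object@ordinals),
              sum(object@counts)))
  if (length(object@droppedTrials))
    cat(sprintf("  %d step(s) dropped near recording edges\n",
                length(object@droppedTrials)))
})

#' RateProfile: spikes-per-EOD along a movement trajectory
#'
#' Position-resolved firing-rate profile for moving-object sweeps: each EOD
#' is assigned to the 1 mm position bin of the object at its emission time,
#' and the per-bin rate is the number of spikes following those EODs divided
#' by the number of EODs in the bin.
#'
#' @slot positions bin centers (mm).
#' @slot rates spikes per EOD in each bin.
#' @slot nEODs EODs per bin.
#' @slot direction `"rostral_to_caudal"` or `"caudal_to_rostral"`.
#' @slot excludedEODs number of EODs outside the position trace.
#' @seealso [positionRateProfile()], [directionContrast()]
#' @export
setClass("RateProfile",
  representation(positions = "numeric", rates = "numeric",
                 nEODs = "integer", direction = "character",
                 excludedEODs = "integer"))

setValidity("RateProfile", function(object) {
  msg <- character(0)
  if (length(object@positions) != length(object@rates) ||
      length(object@rates) != length(object@nEODs))
    msg <- c(msg, "positions, rates and nEODs must have equal length")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("profilePositions", "RateProfile", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("profileRates", "RateProfile", function(x) x@rates)

#' @rdname accessors
#' @export
setMethod("nEODs", "RateProfile", function(x) x@nEODs)

setMethod("show", "RateProfile", function(object) {
  cat(sprintf("RateProfile (%s): %d bins spanning %.0f-%.0f mm, peak %.3f spikes/EOD\n",
              object@direction, length(object@positions),
              min(object@positions), max(object@positions),
              if (length(object@rates)) max(object@rates) else NA_real_))
})

#' ClusterResult: unit-type classification by Ward clustering
#'
#' Result of hierarchically clustering unit-sum post-EOD histograms:
#' the Ward linkage tree, the Davies-Bouldin curve over candidate cluster
#' counts, the selected count, per-unit labels, and per-cluster percentile
#' profiles of the peri-EOD histograms.
#'
#' @slot tree an [stats::hclust] object (Ward linkage).
#' @slot dbCurve named numeric, Davies-Bouldin index per candidate k.
#' @slot chosenK selected number of clusters.
#' @slot labels named integer, cluster label per unit.
#' @slot profiles list of per-cluster percentile-curve matrices.
#' @slot kSelection `"elbow"` or `"manual"`.
#' @seealso [classifyUnits()], [selectKElbow()]
#' @export
setClass("ClusterResult",
  representation(tree = "ANY", dbCurve = "numeric", chosenK = "integer",
                 labels = "integer", profiles = "list",
                 kSelection = "character"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("chosenK", "ClusterResult", function(x) x@chosenK)

#' @rdname accessors
#' @export
setMethod("dbCurve", "ClusterResult", function(x) x@dbCurve)

#' @rdname accessors
#' @export
setMethod("clusterTree", "ClusterResult", function(x) x@tree)

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d units, k = %d (%s selection)\n",
              length(object@labels), object@chosenK, object@kSelection))
  print(table(object@labels))
})
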