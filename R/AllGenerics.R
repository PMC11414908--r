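#' Accessor generics
#'
#' Small family of generics giving read access to the slots of the central
#' data objects (\linkS4class{EventSeries}, \linkS4class{PeriEODHistogram},
#' \linkS4class{OrdinalAlignment}, \linkS4class{RateProfile},
#' \linkS4class{ClusterResult}).  Accessors are the supported interface;
#' slots are internal.
#'
#' @param x an object of one of the classes above.
#' @return The corresponding component (see the class documentation).
#' @name accessors
#' @aliases eventTimes eventKind unitLabel nEvents binCenters histValues
#'   histNormalization nEODs nSpikes blankedBins ordinalIndex ordinalCounts
#'   ordinalLatencies profilePositions profileRates clusterLabels chosenK
#'   dbCurve clusterTree
NULL

#' @rdname accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))

#' @rdname accessors
#' @export
setGeneric("eventKind", function(x) standardGeneric("eventKind"))

#' @rdname accessors
#' @export
setGeneric("unitLabel", function(x) standardGeneric("unitLabel"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("histValues", function(x) standardGeneric("histValues"))

#' @rdname accessors
#' @export
setGeneric("histNormalization", function(x) standardGeneric("histNormalization"))

#' @rdname accessors
#' @export
setGeneric("nEODs", function(x) standardGeneric("nEODs"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("blankedBins", function(x) standardGeneric("blankedBins"))

#' @rdname accessors
#' @export
setGeneric("ordinalIndex", function(x) standardGeneric("ordinalIndex"))

#' @rdname accessors
#' @export
setGeneric("ordinalCounts", function(x) standardGeneric("ordinalCounts"))

#' @rdname accessors
#' @export
setGeneric("ordinalLatencies", function(x) standardGeneric("ordinalLatencies"))

#' @rdname accessors
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))

#' @rdname accessors
#' @export
setGeneric("profileRates", function(x) standardGeneric("profileRates"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setGeneric("dbCurve", function(x) standardGeneric("dbCurve"))

#' @rdname accessors
#' @export
setGeneric("clusterTree", function(x) standardGeneric("clusterTree"))
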