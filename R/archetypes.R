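#' UnitArchetype: generative model of one firing-pattern type
#'
#' Phenomenological description of how one electrosensory-lobe unit type
#' responds to each EOD.  The conditional intensity within an inter-EOD
#' interval is a mixture of Gaussian latency modes plus a uniform baseline,
#' gated by multiplicative inhibition windows; per-interval spike counts are
#' Poisson (truncated at 4) with a mean given by the summed mode weights and
#' the baseline mass, scaled by a stimulus-dependent count gain that decays
#' back to 1 with an e-fold constant of `adaptationTau` EODs after every
#' stimulus step.  Primary spikes may be expanded into short-ISI bursts
#' (doublets/triplets).  A Mexican-hat receptive-field profile with optional
#' direction asymmetry modulates the gain for moving objects.
#'
#' @slot name one of `sharp_monomodal`, `broad_monomodal`, `bimodal`,
#'   `trimodal`, `mildly_inhibited`, `deeply_inhibited` (free-form labels are
#'   allowed for custom archetypes).
#' @slot modes matrix with columns `latency`, `sd`, `weight`: Gaussian
#'   latency modes (ms, ms, expected spikes/EOD).
#' @slot inhibition matrix with columns `start`, `end`, `depth`: windows
#'   (ms after the EOD) in which a candidate spike is deleted with
#'   probability `depth`.
#' @slot baselineRate uniform background rate (spikes/s).
#' @slot burst numeric `(prob, isi, size)`: probability that a primary spike
#'   is expanded into a burst, the intra-burst ISI (ms), and the maximal
#'   burst size (>= 2).
#' @slot countGainUp,countGainDown multiplicative count gain applied at a
#'   stimulus increase/decrease (>= 0), decaying to 1.
#' @slot adaptationTau e-fold constant of the phasic gain decay (EODs).
#' @slot timingShift latency shift (ms) added to the mode centers while the
#'   stimulus sits at its high level; 0 disables timing modulation.
#' @slot rfProfile list `(center, ampExc, ampInh, widthExc, widthInh, asym,
#'   asymSign)`: Mexican-hat receptive field (mm) and the post-center
#'   suppression factor applied when moving in the direction `asymSign`.
#' @seealso [unitArchetype()], [defaultArchetypes()], [generateUnitSpikes()]
#' @export
setClass("UnitArchetype",
  representation(name = "character", modes = "matrix", inhibition = "matrix",
                 baselineRate = "numeric", burst = "numeric",
                 countGainUp = "numeric", countGainDown = "numeric",
                 adaptationTau = "numeric", timingShift = "numeric",
                 rfProfile = "list"))

setValidity("UnitArchetype", function(object) {
  msg <- character(0)
  m <- object@modes
  if (nrow(m)) {
    if (any(m[, "latency"] <= 2.5 | m[, "latency"] >= 40))
      msg <- c(msg, "mode latencies must lie in (2.5, 40) ms")
    if (any(m[, "sd"] <= 0)) msg <- c(msg, "mode sds must be positive")
    if (any(m[, "weight"] < 0)) msg <- c(msg, "mode weights must be >= 0")
    if (sum(m[, "weight"]) > 4)
      msg <- c(msg, "summed mode weights exceed the 4 spikes/EOD budget")
  }
  ih <- object@inhibition
  if (nrow(ih)) {
    if (any(ih[, "start"] >= ih[, "end"]))
      msg <- c(msg, "inhibition windows must have start < end")
    if (any(ih[, "depth"] < 0 | ih[, "depth"] > 1))
      msg <- c(msg, "inhibition depth must lie in [0, 1]")
  }
  if (object@baselineRate < 0) msg <- c(msg, "baselineRate must be >= 0")
  b <- object@burst
  if (length(b) != 3L || b[1L] < 0 || b[1L] > 1 || b[2L] <= 0 || b[3L] < 2)
    msg <- c(msg, "burst must be (prob in [0,1], isi > 0, size >= 2)")
  if (object@countGainUp < 0 || object@countGainDown < 0)
    msg <- c(msg, "count gains must be >= 0")
  if (object@adaptationTau <= 0) msg <- c(msg, "adaptationTau must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a unit archetype
#'
#' @param name archetype label.
#' @param modes matrix (or 3-column coercible) of latency modes: columns
#'   `latency` (ms), `sd` (ms), `weight` (expected spikes/EOD).
#' @param inhibition matrix of inhibition windows: columns `start`, `end`
#'   (ms), `depth` (deletion probability).
#' @param baselineRate background rate, spikes/s.
#' @param burst numeric `(prob, isi, size)`.
#' @param countGainUp,countGainDown phasic count gains at stimulus steps.
#' @param adaptationTau gain-decay e-fold constant, in EODs (default 8).
#' @param timingShift mode-latency shift (ms) at the high stimulus level.
#' @param rfProfile receptive-field parameter list; see
#'   \linkS4class{UnitArchetype}.
#' @return A \linkS4class{UnitArchetype}.
#' @examples
#' a <- unitArchetype("demo", modes = c(10, 0.5, 1))
#' a
#' @export
unitArchetype <- function(name,
                          modes = NULL,
                          inhibition = NULL,
                          baselineRate = 0,
                          burst = c(0, 4, 2),
                          countGainUp = 1, countGainDown = 1,
                          adaptationTau = 8,
                          timingShift = 0,
                          rfProfile = list(center = 10, ampExc = 0, ampInh = 0,
                                           widthExc = 5, widthInh = 12,
                                           asym = 0, asymSign = -1)) {
  toMat <- function(x, cols) {
    if (is.null(x)) return(matrix(numeric(0), 0, length(cols),
                                  dimnames = list(NULL, cols)))
    x <- matrix(as.numeric(x), ncol = length(cols), byrow = !is.matrix(x))
    colnames(x) <- cols
    x
  }
  new("UnitArchetype", name = as.character(name),
      modes = toMat(modes, c("latency", "sd", "weight")),
      inhibition = toMat(inhibition, c("start", "end", "depth")),
      baselineRate = baselineRate, burst = as.numeric(burst),
      countGainUp = countGainUp, countGainDown = countGainDown,
      adaptationTau = adaptationTau, timingShift = timingShift,
      rfProfile = rfProfile)
}

setMethod("show", "UnitArchetype", function(object) {
  cat(sprintf("UnitArchetype '%s': %d mode(s), baseline %.2g spikes/s, burst p = %.2g\n",
              object@name, nrow(object@modes), object@baselineRate,
              object@burst[1L]))
})

#' The six default firing-pattern archetypes
#'
#' Returns the calibrated population of six archetypes mirroring the unit
#' types seen in the centro-medial electrosensory lobe: sharp monomodal
#' (silenced by the EOD, sharp 10--12 ms peak, bursts of 2--3 spikes), broad
#' monomodal (broad mode near 23 ms), bimodal (sharp 10--12 ms plus broad
#' 15--25 ms), trimodal (as bimodal plus an occasional 5 ms spike), mildly
#' inhibited (firing concentrated immediately after the EOD and late in the
#' interval, with brief dips near 5 and 10 ms) and deeply inhibited (sharp
#' suppression from about 5 ms with a slow late recovery).
#'
#' The default parameters are calibrated so that, at the default EOD rate
#' (mean interval 44.5 ms), the population jointly reproduces a grand mean
#' of about 0.35 spikes/EOD and a grand mean inter-spike interval (over ISIs
#' up to the 300 ms correlation horizon) of about 84 ms, and so that
#' "center-on" types (broad monomodal, bimodal, trimodal) increase their
#' counts at stimulus increases while "center-off" types (sharp monomodal,
#' mildly and deeply inhibited) decrease them.
#'
#' @return Named list of six \linkS4class{UnitArchetype} objects.
#' @examples
#' names(defaultArchetypes())
#' @export
defaultArchetypes <- function() {
  rf <- function(center, ampExc, ampInh, widthExc = 6, widthInh = 16,
                 asym = 0.5, asymSign = -1)
    list(center = center, ampExc = ampExc, ampInh = ampInh,
         widthExc = widthExc, widthInh = widthInh,
         asym = asym, asymSign = asymSign)
  list(
    sharp_monomodal = unitArchetype(
      "sharp_monomodal",
      modes = c(11, 0.7, 0.1833),
      inhibition = c(2.5, 8.5, 0.92),
      baselineRate = 0.825,
      burst = c(0.38, 3.5, 3),
      countGainUp = 0.35, countGainDown = 3,
      rfProfile = rf(15, -0.8, -0.5, 6, 18)),
    broad_monomodal = unitArchetype(
      "broad_monomodal",
      modes = c(24.5, 4.5, 0.2867),
      inhibition = c(2.5, 11, 0.85),
      baselineRate = 0.922,
      burst = c(0.12, 4, 2),
      countGainUp = 3, countGainDown = 0.15,
      rfProfile = rf(25, 1.5, 0.6)),
    bimodal = unitArchetype(
      "bimodal",
      modes = rbind(c(10.5, 1.2, 0.1129),
                    c(17.5, 2.0, 0.1571)),
      inhibition = c(2.5, 8, 0.9),
      baselineRate = 0.540,
      burst = c(0.22, 4, 2),
      countGainUp = 3, countGainDown = 0.15,
      rfProfile = rf(35, 1.8, 0.8)),
    trimodal = unitArchetype(
      "trimodal",
      modes = rbind(c(5, 0.5, 0.0943),
                    c(12, 1.0, 0.0943),
                    c(27, 4.5, 0.0794)),
      inhibition = c(6.5, 9.5, 0.85),
      baselineRate = 0.546,
      burst = c(0.22, 4, 2),
      countGainUp = 3, countGainDown = 0.3,
      rfProfile = rf(10, 1.5, 0.7)),
    mildly_inhibited = unitArchetype(
      "mildly_inhibited",
      modes = rbind(c(3.2, 0.5, 0.0889),
                    c(29, 4.5, 0.1156)),
      inhibition = rbind(c(4.5, 6.5, 0.8),
                         c(9.5, 11.5, 0.6)),
      baselineRate = 2.846,
      burst = c(0.12, 4, 2),
      countGainUp = 0.3, countGainDown = 3,
      rfProfile = rf(45, -0.9, -0.4, 8, 20)),
    deeply_inhibited = unitArchetype(
      "deeply_inhibited",
      modes = c(39, 3.5, 0.2465),
      inhibition = c(2.5, 22, 0.97),
      baselineRate = 7.284,
      burst = c(0.08, 4, 2),
      countGainUp = 0.4, countGainDown = 2.5,
      rfProfile = rf(55, -1, -0.5, 8, 22))
  )
}

#' Jitter an archetype into an individual unit
#'
#' Draws a unit-level variant of an archetype: mode latencies receive small
#' Gaussian offsets and widths/weights/baseline small log-normal factors, so
#' that units of the same type share a firing pattern without being clones.
#' Uses the current RNG state.
#'
#' @param archetype a \linkS4class{UnitArchetype}.
#' @param sdLatency sd of the latency offset (ms).
#' @param sdLogScale sd of the log-normal factors.
#' @return A new \linkS4class{UnitArchetype}.
#' @export
jitterArchetype <- function(archetype, sdLatency = 0.2, sdLogScale = 0.07) {
  a <- archetype
  m <- a@modes
  if (nrow(m)) {
    m[, "latency"] <- pmin(pmax(m[, "latency"] +
                                  rnorm(nrow(m), 0, sdLatency), 2.6), 39.5)
    m[, "sd"] <- m[, "sd"] * exp(rnorm(nrow(m), 0, sdLogScale))
    m[, "weight"] <- m[, "weight"] * exp(rnorm(nrow(m), 0, sdLogScale))
    a@modes <- m
  }
  a@baselineRate <- a@baselineRate * exp(rnorm(1, 0, sdLogScale))
  validObject(a)
  a
}
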