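#' Generate a renewal EOD train
#'
#' Inter-EOD intervals are drawn from a gamma renewal process with mean
#' `meanInterval` and shape `shape`; the default shape of 50 gives the low
#' interval jitter (cv about 0.14) typical of resting discharge rhythms,
#' while the default mean interval of 44.5 ms corresponds to 22.5 EOD/s.
#'
#' @param nEods number of EODs to generate (mutually exclusive with
#'   `duration`).
#' @param duration recording duration in seconds; the train holds every EOD
#'   emitted up to `duration` (possibly none).
#' @param meanInterval mean inter-EOD interval (ms).
#' @param shape gamma renewal shape parameter (dimensionless).
#' @param seed optional integer seed; when given, the train is a
#'   deterministic function of the parameters.
#' @return An \linkS4class{EventSeries} of kind `"EOD"`.
#' @examples
#' eods <- generateEODTrain(nEods = 200, seed = 1)
#' mean(diff(eventTimes(eods)))
#' @export
generateEODTrain <- function(nEods = NULL, duration = NULL,
                             meanInterval = 44.5, shape = 50, seed = NULL) {
  if (meanInterval <= 0 || shape <= 0)
    stop("meanInterval and shape must be positive")
  if (is.null(nEods) == is.null(duration))
    stop("give exactly one of 'nEods' or 'duration'")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(nEods)) {
    if (nEods < 1) stop("nEods must be >= 1")
    iv <- rgamma(nEods, shape = shape, rate = shape / meanInterval)
    times <- cumsum(iv)
  } else {
    if (duration <= 0) stop("duration must be positive")
    durMs <- duration * 1000
    n <- ceiling(durMs / meanInterval * 1.25 + 4 * sqrt(durMs / meanInterval)) + 10
    iv <- rgamma(n, shape = shape, rate = shape / meanInterval)
    times <- cumsum(iv)
    while (times[length(times)] < durMs) {   # extremely unlikely top-up
      iv <- rgamma(n, shape = shape, rate = shape / meanInterval)
      times <- c(times, times[length(times)] + cumsum(iv))
    }
    times <- times[times <= durMs]
  }
  EventSeries(times, kind = "EOD")
}

## Per-EOD count gain and timing shift implied by a stimulus level sequence:
## at each level change the gain jumps to countGainUp/Down and decays
## exponentially back to 1 with e-fold adaptationTau EODs; the timing shift
## applies while the level sits above its minimum.
.stimulusModulation <- function(archetype, levels) {
  n <- length(levels)
  gain <- rep(1, n)
  shift <- rep(0, n)
  if (n == 0L || length(unique(levels)) == 1L)
    return(list(gain = gain, shift = shift))
  chg <- which(diff(levels) != 0) + 1L
  bounds <- c(chg, n + 1L)
  for (i in seq_along(chg)) {
    idx <- chg[i]:(bounds[i + 1L] - 1L)
    G <- if (levels[chg[i]] > levels[chg[i] - 1L])
      archetype@countGainUp else archetype@countGainDown
    k <- seq_along(idx) - 1L
    gain[idx] <- 1 + (G - 1) * exp(-k / archetype@adaptationTau)
  }
  if (archetype@timingShift != 0)
    shift[levels > min(levels)] <- archetype@timingShift
  list(gain = gain, shift = shift)
}

## Sampling core shared by all spike generators.  et: EOD times (ms);
## gain, shift: per-interval count gain and mode-latency shift (length
## length(et) - 1).  Returns list(times, perIntervalCount).
.drawSpikes <- function(et, archetype, gain, shift) {
  nIv <- length(et) - 1L
  if (nIv <= 0L)
    return(list(times = numeric(0), perIntervalCount = integer(0)))
  iv <- diff(et)
  m <- archetype@modes
  wModes <- if (nrow(m)) m[, "weight"] else numeric(0)
  wBase <- archetype@baselineRate * iv / 1000
  lam <- (sum(wModes) + wBase) * pmax(gain, 0)
  counts <- pmin(rpois(nIv, lam), 4L)
  tot <- sum(counts)
  if (tot == 0L)
    return(list(times = numeric(0), perIntervalCount = counts))

  sIv <- rep.int(seq_len(nIv), counts)          # interval of each spike
  len <- iv[sIv]
  pBase <- wBase[sIv] / (sum(wModes) + wBase[sIv])
  isBase <- runif(tot) < pBase
  lat <- numeric(tot)
  if (any(isBase))
    lat[isBase] <- runif(sum(isBase), 2.5, pmax(len[isBase] - 2.5, 2.5))
  if (any(!isBase)) {
    k <- sum(!isBase)
    comp <- sample.int(nrow(m), k, replace = TRUE, prob = wModes)
    lat[!isBase] <- rnorm(k, m[comp, "latency"] + shift[sIv[!isBase]],
                          m[comp, "sd"])
  }
  keep <- lat > 2.5 & lat < len - 2.5            # blanking convention
  ih <- archetype@inhibition
  if (nrow(ih) && any(keep)) {
    for (w in seq_len(nrow(ih))) {               # rejection thinning
      inWin <- keep & lat >= ih[w, "start"] & lat < ih[w, "end"]
      if (any(inWin))
        keep[inWin] <- keep[inWin] & (runif(sum(inWin)) >= ih[w, "depth"])
    }
  }
  sIv <- sIv[keep]; lat <- lat[keep]; len <- len[keep]

  b <- archetype@burst                           # burst expansion last
  if (b[1L] > 0 && length(lat)) {
    doBurst <- runif(length(lat)) < b[1L]
    if (any(doBurst)) {
      nExtra <- sample.int(b[3L] - 1L, sum(doBurst), replace = TRUE)
      xIv <- rep.int(sIv[doBurst], nExtra)
      xLen <- rep.int(len[doBurst], nExtra)
      xLat <- rep.int(lat[doBurst], nExtra) +
        b[2L] * unlist(lapply(nExtra, seq_len), use.names = FALSE)
      ok <- xLat < xLen - 2.5
      sIv <- c(sIv, xIv[ok]); lat <- c(lat, xLat[ok])
    }
  }
  times <- sort(et[sIv] + lat)
  times <- times[c(TRUE, diff(times) > 1e-9)]    # point process: no ties
  list(times = times, perIntervalCount = tabulate(sIv, nbins = nIv))
}

#' Generate the spike train of one unit responding to an EOD train
#'
#' Spikes are drawn independently for every inter-EOD interval: the expected
#' count is the summed mode weight plus the baseline mass of the interval,
#' multiplied by the stimulus count gain; counts are Poisson truncated at 4
#' spikes per interval; latencies are sampled from the weighted mixture of
#' Gaussian modes and the uniform baseline, thinned by the archetype's
#' inhibition windows (rejection with probability `depth`); surviving
#' primary spikes are expanded into short-ISI bursts.  No spike is placed
#' within 2.5 ms of either flanking EOD, so the generator respects the
#' blanking convention of the analyses.
#'
#' @param eods an \linkS4class{EventSeries} of kind `"EOD"` (non-empty).
#' @param archetype a \linkS4class{UnitArchetype}.
#' @param stimulus optional numeric vector of per-EOD stimulus levels (same
#'   length as the EOD train); level changes trigger the phasic count gain
#'   and, if configured, the timing shift.
#' @param unitId label for the returned series.
#' @param seed optional integer seed.
#' @param detail if `TRUE`, also return the generator's per-interval ledger.
#' @return An \linkS4class{EventSeries} of spikes, or (with `detail = TRUE`)
#'   a list with elements `spikes` and `perInterval` (data frame with the
#'   EOD index, realized spike count and applied gain).
#' @examples
#' eods <- generateEODTrain(nEods = 500, seed = 1)
#' sp <- generateUnitSpikes(eods, defaultArchetypes()$bimodal, seed = 2)
#' nEvents(sp) / nEvents(eods)
#' @export
generateUnitSpikes <- function(eods, archetype, stimulus = NULL,
                               unitId = NA_character_, seed = NULL,
                               detail = FALSE) {
  stopifnot(is(eods, "EventSeries"), is(archetype, "UnitArchetype"))
  et <- eventTimes(eods)
  nE <- length(et)
  if (nE == 0L) stop("EOD train is empty")
  if (!is.null(stimulus) && length(stimulus) != nE)
    stop(sprintf("stimulus length (%d) must equal the number of EODs (%d)",
                 length(stimulus), nE))
  if (!is.null(seed)) set.seed(seed)
  nIv <- max(nE - 1L, 0L)
  mod <- .stimulusModulation(archetype,
                             if (is.null(stimulus)) rep(1, nIv)
                             else stimulus[seq_len(nIv)])
  drawn <- .drawSpikes(et, archetype, mod$gain, mod$shift)
  spikes <- EventSeries(drawn$times, kind = "spike", unitId = unitId)
  if (detail)
    return(list(spikes = spikes,
                perInterval = data.frame(eodIndex = seq_len(nIv),
                                         count = as.integer(drawn$perIntervalCount),
                                         gain = mod$gain)))
  spikes
}

#' Simulate a baseline population of the six archetypes
#'
#' Draws `nPerType` units per archetype, each with its own EOD train of
#' `nEods` discharges and unit-level parameter jitter (see
#' [jitterArchetype()]), in the absence of any stimulus object.
#'
#' @param nPerType units per archetype (default 17, i.e. 102 units in all).
#' @param nEods EODs per unit (default 500).
#' @param meanInterval,shape EOD train parameters.
#' @param seed integer seed for the whole cohort.
#' @param jitter logical; draw unit-level parameter variability?
#' @param archetypes archetype list (defaults to [defaultArchetypes()]).
#' @return A list with `units` (named list; each element has `unitId`,
#'   `type`, `eods`, `spikes`) and `truth` (data frame `unit_id`,
#'   `archetype`).
#' @examples
#' pop <- generatePopulation(nPerType = 2, nEods = 100, seed = 1)
#' pop$truth
#' @export
generatePopulation <- function(nPerType = 17, nEods = 500,
                               meanInterval = 44.5, shape = 50, seed = NULL,
                               jitter = TRUE, archetypes = defaultArchetypes()) {
  if (!is.null(seed)) set.seed(seed)
  units <- list()
  for (ty in names(archetypes)) {
    for (i in seq_len(nPerType)) {
      uid <- sprintf("%s_%02d", ty, i)
      a <- if (jitter) jitterArchetype(archetypes[[ty]]) else archetypes[[ty]]
      eods <- generateEODTrain(nEods = nEods, meanInterval = meanInterval,
                               shape = shape)
      spikes <- generateUnitSpikes(eods, a, unitId = uid)
      units[[uid]] <- list(unitId = uid, type = ty, eods = eods,
                           spikes = spikes)
    }
  }
  truth <- data.frame(unit_id = vapply(units, `[[`, "", "unitId"),
                      archetype = vapply(units, `[[`, "", "type"),
                      row.names = NULL)
  list(units = units, truth = truth)
}

#' Step-stimulation protocol
#'
#' @param levelLow,levelHigh stimulus amplitudes (arbitrary units; the
#'   default ratio is 3, matching the three-fold steps used in the
#'   impedance-switching experiments).
#' @param dutyLong,dutyShort durations (s) of the long baseline phase and
#'   the short stepped phase of each duty cycle (defaults 28 s and 2 s).
#' @param nTrials number of duty cycles (default 16).
#' @param direction `"up"` (long phase at the low level, step increases the
#'   stimulus) or `"down"`.
#' @return A parameter list used by [generateStepExperiment()].
#' @export
stepProtocol <- function(levelLow = 1, levelHigh = 3, dutyLong = 28,
                         dutyShort = 2, nTrials = 16,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (levelHigh <= levelLow) stop("levelHigh must exceed levelLow")
  list(levelLow = levelLow, levelHigh = levelHigh, dutyLong = dutyLong,
       dutyShort = dutyShort, nTrials = nTrials, direction = direction)
}

#' Simulate a stimulus-step experiment for one unit
#'
#' The stimulus alternates between a long phase at one level and a short
#' phase at the other, for `nTrials` duty cycles; the analyzed steps are the
#' long-to-short transitions.  Both phases must be long enough to hold the
#' 25 flanking EODs required by the ordinal analysis.
#'
#' @param archetype a \linkS4class{UnitArchetype}.
#' @param protocol a [stepProtocol()].
#' @param meanInterval,shape EOD train parameters.
#' @param seed optional integer seed.
#' @return A list: `spikes`, `eods` (\linkS4class{EventSeries}), `levels`
#'   (per-EOD stimulus level), `stepTimes` (ms), `schedule` (data frame
#'   `t_on_s`, `level`), and `truth` (per-interval generator ledger).
#' @examples
#' ex <- generateStepExperiment(defaultArchetypes()$bimodal,
#'                              stepProtocol(nTrials = 2), seed = 1)
#' length(ex$stepTimes)
#' @export
generateStepExperiment <- function(archetype, protocol = stepProtocol(),
                                   meanInterval = 44.5, shape = 50,
                                   seed = NULL) {
  need <- 27 * meanInterval / 1000        # 25 flanking EODs plus margin
  if (protocol$dutyShort < need || protocol$dutyLong < need)
    stop(sprintf(
      "duty phases must each exceed %.1f s to hold 25 flanking EODs", need))
  if (!is.null(seed)) set.seed(seed)
  longLv <- if (protocol$direction == "up") protocol$levelLow else protocol$levelHigh
  shortLv <- if (protocol$direction == "up") protocol$levelHigh else protocol$levelLow
  cyc <- protocol$dutyLong + protocol$dutyShort
  tOn <- rep(seq_len(protocol$nTrials) - 1L, each = 2L) * cyc +
    c(0, protocol$dutyLong)
  schedule <- data.frame(t_on_s = tOn,
                         level = rep(c(longLv, shortLv), protocol$nTrials))
  total <- protocol$nTrials * cyc
  eods <- generateEODTrain(duration = total, meanInterval = meanInterval,
                           shape = shape)
  et <- eventTimes(eods)
  phase <- findInterval(et, schedule$t_on_s * 1000)
  levels <- schedule$level[pmax(phase, 1L)]
  stepTimes <- (schedule$t_on_s * 1000)[seq(2L, nrow(schedule), by = 2L)]
  gen <- generateUnitSpikes(eods, archetype, stimulus = levels,
                            unitId = archetype@name, detail = TRUE)
  list(spikes = gen$spikes, eods = eods, levels = levels,
       stepTimes = stepTimes, schedule = schedule, truth = gen$perInterval)
}

#' Simulate a moving-object sweep for one unit
#'
#' A vertical object is moved along the skin at constant speed; the unit's
#' count gain at each EOD is given by its Mexican-hat receptive-field
#' profile evaluated at the object position, with optional post-center
#' suppression when the motion direction matches the configured asymmetry
#' sign.
#'
#' @param archetype a \linkS4class{UnitArchetype}.
#' @param sweep list `(start, end, speed)`: start/end positions (mm) and
#'   speed (mm/s); `end < start` sweeps in the caudal-to-rostral direction.
#' @param meanInterval,shape EOD train parameters.
#' @param seed optional integer seed.
#' @return A list: `spikes`, `eods`, `trace` (data frame `time_ms`,
#'   `position_mm`), `positions` (object position at each EOD), `gains`,
#'   `direction`.
#' @examples
#' ex <- generateMovingObjectExperiment(defaultArchetypes()$broad_monomodal,
#'                                      sweep = list(start = 0, end = 50,
#'                                                   speed = 2), seed = 1)
#' range(ex$positions)
#' @export
generateMovingObjectExperiment <- function(archetype,
                                           sweep = list(start = 0, end = 100,
                                                        speed = 1),
                                           meanInterval = 44.5, shape = 50,
                                           seed = NULL) {
  if (sweep$speed <= 0) stop("sweep speed must be positive")
  if (sweep$end == sweep$start) stop("zero-length sweep")
  if (!is.null(seed)) set.seed(seed)
  dirSign <- sign(sweep$end - sweep$start)
  duration <- abs(sweep$end - sweep$start) / sweep$speed
  eods <- generateEODTrain(duration = duration, meanInterval = meanInterval,
                           shape = shape)
  et <- eventTimes(eods)
  pos <- sweep$start + dirSign * sweep$speed * et / 1000
  gains <- rfGain(archetype@rfProfile, pos, motionSign = dirSign)
  nIv <- max(length(et) - 1L, 0L)
  drawn <- .drawSpikes(et, archetype, gains[seq_len(nIv)], rep(0, nIv))
  spikes <- EventSeries(drawn$times, kind = "spike", unitId = archetype@name)
  trace <- data.frame(time_ms = c(0, et, duration * 1000),
                      position_mm = sweep$start +
                        dirSign * sweep$speed * c(0, et, duration * 1000) / 1000)
  list(spikes = spikes, eods = eods, trace = trace, positions = pos,
       gains = gains, direction = if (dirSign > 0) "rostral_to_caudal"
                                  else "caudal_to_rostral")
}

#' Receptive-field gain profile
#'
#' Mexican-hat gain: `1 + ampExc * exp(-(x - center)^2 / (2 widthExc^2)) -
#' ampInh * exp(-(x - center)^2 / (2 widthInh^2))`, clipped at zero.
#' Negative `ampExc` values describe center-off fields.  When the motion
#' direction matches `asymSign`, positions already passed by the object are
#' additionally suppressed by the factor `1 - asym`.
#'
#' @param profile receptive-field parameter list (see
#'   \linkS4class{UnitArchetype}).
#' @param x positions (mm).
#' @param motionSign +1 for rostral-to-caudal motion, -1 for the reverse;
#'   `0` disables the direction asymmetry.
#' @return Numeric gain vector, same length as `x`.
#' @export
rfGain <- function(profile, x, motionSign = 0) {
  g <- 1 +
    profile$ampExc * exp(-(x - profile$center)^2 / (2 * profile$widthExc^2)) -
    profile$ampInh * exp(-(x - profile$center)^2 / (2 * profile$widthInh^2))
  if (motionSign != 0 && profile$asym > 0 && motionSign == profile$asymSign) {
    passed <- if (motionSign > 0) x > profile$center else x < profile$center
    g[passed] <- g[passed] * (1 - profile$asym)
  }
  pmax(g, 0)
}

#' Per-unit baseline summary statistics
#'
#' Spikes per EOD and mean inter-spike interval for each unit of a
#' population, plus the grand means across units.  The mean ISI is computed
#' over ISIs up to `isiHorizon` ms (default 300 ms, the cross-correlation
#' analysis horizon), so that long silent stretches between response packets
#' do not enter the interval statistics.
#'
#' @param population result of [generatePopulation()], or any list of units
#'   with `eods` and `spikes` elements.
#' @param isiHorizon upper bound (ms) for ISIs entering the mean.
#' @return A list with `perUnit` (data frame `unit_id`, `spikes_per_eod`,
#'   `mean_isi_ms`) and `grand` (named numeric with the two grand means).
#' @export
baselineSummary <- function(population, isiHorizon = 300) {
  units <- if (!is.null(population$units)) population$units else population
  per <- lapply(units, function(u) {
    nS <- nEvents(u$spikes); nE <- nEvents(u$eods)
    isi <- diff(eventTimes(u$spikes))
    isi <- isi[isi <= isiHorizon]
    data.frame(unit_id = u$unitId,
               spikes_per_eod = nS / nE,
               mean_isi_ms = if (length(isi)) mean(isi) else NA_real_)
  })
  perUnit <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  list(perUnit = perUnit,
       grand = c(spikes_per_eod = mean(perUnit$spikes_per_eod),
                 mean_isi_ms = mean(perUnit$mean_isi_ms, na.rm = TRUE)))
}
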