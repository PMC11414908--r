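#' Pipeline configuration
#'
#' Assembles the parameter set of the full analysis pipeline.  The defaults
#' are the canonical analysis parameters: a closed \[-2.5, +2.5\] ms
#' blanking window, 1 ms bins, a -200..+300 ms cross-correlation window, a
#' -15..+40 ms profile window, a 2.5--40 ms post-EOD window, 25/3-EOD
#' Friedman repetition counts, and the triads -25..-4, -3..-1, 0..2,
#' 23..25.
#'
#' @param blanking blanking window (ms).
#' @param ccWindow cross-correlation window (ms).
#' @param profileWindow peri-EOD profile window (ms).
#' @param postWindow post-EOD histogram window (ms).
#' @param binWidth histogram bin width (ms).
#' @param kRange candidate cluster counts.
#' @param k `"auto"` or an integer override for the cluster count.
#' @param dbVariant Davies-Bouldin variant.
#' @param triads triad definitions (see [defaultTriads()]).
#' @param alphas significance levels.
#' @param minEods,minSpikes minimum-data thresholds.
#' @param nPerType,nEods cohort size of the simulated population.
#' @param meanInterval,shape EOD train parameters.
#' @param nStepUnits,nStepTrials step-experiment cohort per type.
#' @param stepTypes archetypes studied in the step stage.
#' @param seed root seed; all pipeline randomness derives from it.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(blanking = c(-2.5, 2.5),
                           ccWindow = c(-200, 300),
                           profileWindow = c(-15, 40),
                           postWindow = c(2.5, 40),
                           binWidth = 1,
                           kRange = 2:12,
                           k = "auto",
                           dbVariant = "centroid",
                           triads = defaultTriads(),
                           alphas = c(0.05, 0.01, 0.001),
                           minEods = 500, minSpikes = 100,
                           nPerType = 17, nEods = 500,
                           meanInterval = 44.5, shape = 50,
                           nStepUnits = 8, nStepTrials = 16,
                           stepTypes = c("sharp_monomodal", "broad_monomodal",
                                         "mildly_inhibited", "bimodal"),
                           seed = 1) {
  cfg <- list(blanking = blanking, ccWindow = ccWindow,
              profileWindow = profileWindow, postWindow = postWindow,
              binWidth = binWidth, kRange = kRange, k = k,
              dbVariant = dbVariant, triads = triads, alphas = alphas,
              minEods = minEods, minSpikes = minSpikes,
              nPerType = nPerType, nEods = nEods,
              meanInterval = meanInterval, shape = shape,
              nStepUnits = nStepUnits, nStepTrials = nStepTrials,
              stepTypes = stepTypes, seed = seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Step-experiment battery for one unit type
#'
#' Simulates `nUnits` units of one archetype, runs upward and downward step
#' protocols on each, aligns the spikes to the ordinal EODs and pools the
#' triad distributions.
#'
#' @param archetype a \linkS4class{UnitArchetype}.
#' @param nUnits number of units.
#' @param nTrials duty cycles per direction.
#' @param triads triad definitions.
#' @param meanInterval,shape EOD train parameters.
#' @param jitter draw unit-level parameter variability?
#' @return A list per unit with `up`/`down` elements, each holding the
#'   \linkS4class{OrdinalAlignment} (`alignment`) and the triads
#'   (`triads`).
#' @export
stepBattery <- function(archetype, nUnits = 8, nTrials = 16,
                        triads = defaultTriads(),
                        meanInterval = 44.5, shape = 50, jitter = TRUE) {
  out <- list()
  for (i in seq_len(nUnits)) {
    a <- if (jitter) jitterArchetype(archetype) else archetype
    unit <- list()
    for (dir in c("up", "down")) {
      ex <- generateStepExperiment(a, stepProtocol(nTrials = nTrials,
                                                   direction = dir),
                                   meanInterval = meanInterval, shape = shape)
      al <- alignOrdinal(ex$spikes, ex$eods, ex$stepTimes,
                         unitId = sprintf("%s_%02d", archetype@name, i))
      unit[[dir]] <- list(alignment = al,
                          triads = triadDistributions(al, triads))
    }
    out[[sprintf("%s_%02d", archetype@name, i)]] <- unit
  }
  out
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate, blank, filter, histogram, classify, step-response and
#' receptive-field stages on synthetic data with known ground truth, and
#' returns a report bundle with stage-level bookkeeping.  With `outDir`
#' given, the main artifacts (event tables, labels, Davies-Bouldin curve,
#' dendrogram, JSD report) are also written to disk.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory.
#' @return A nested report list; see Details in the package vignette.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  report <- list(provenance = list(
    seed = config$seed,
    package_version = as.character(packageVersion("packetcode")),
    config = config[setdiff(names(config), "triads")],
    timestamp = format(Sys.time(), tz = "UTC")))

  ## stage 1: simulate baseline cohort
  pop <- generatePopulation(nPerType = config$nPerType, nEods = config$nEods,
                            meanInterval = config$meanInterval,
                            shape = config$shape)
  ## stage 2: blanking + minimum-data filter
  for (id in names(pop$units))
    pop$units[[id]]$spikes <- applyBlanking(pop$units[[id]]$spikes,
                                            pop$units[[id]]$eods,
                                            config$blanking)
  retained <- minimumDataFilter(pop$units, config$minEods, config$minSpikes)
  report$filter <- list(n_units = length(pop$units),
                        n_retained = length(retained))
  units <- pop$units[retained]

  ## stage 3: histograms
  post <- lapply(units, function(u)
    postEODHistogram(u$spikes, u$eods, config$postWindow, config$binWidth))
  empty <- vapply(post, is.null, logical(1))
  post <- post[!empty]
  units <- units[!empty]
  cc <- lapply(units, function(u)
    crosscorrHistogram(u$spikes, u$eods, config$ccWindow, config$binWidth,
                       config$blanking))
  report$histograms <- list(n_units = length(post),
                            n_empty_excluded = sum(empty))

  ## stage 4: classification
  cr <- classifyUnits(post, profileHists = cc, kRange = config$kRange,
                      k = config$k, variant = config$dbVariant)
  truth <- pop$truth$archetype[match(names(post), pop$truth$unit_id)]
  report$classification <- list(chosen_k = chosenK(cr),
                                k_selection = cr@kSelection,
                                db_curve = dbCurve(cr),
                                labels = clusterLabels(cr),
                                truth = setNames(truth, names(post)),
                                ari = adjustedRandIndex(clusterLabels(cr),
                                                        truth))

  ## stage 5: step responses + JSD battery
  arch <- defaultArchetypes()
  stepUnits <- list()
  stepTypesOf <- character(0)
  for (ty in config$stepTypes) {
    sb <- stepBattery(arch[[ty]], nUnits = config$nStepUnits,
                      nTrials = config$nStepTrials, triads = config$triads,
                      meanInterval = config$meanInterval,
                      shape = config$shape)
    stepUnits <- c(stepUnits, sb)
    stepTypesOf <- c(stepTypesOf, setNames(rep(ty, length(sb)), names(sb)))
  }
  triadsOnly <- lapply(stepUnits, function(u)
    list(up = u$up$triads, down = u$down$triads))
  friedman <- lapply(split(names(stepUnits), stepTypesOf[names(stepUnits)]),
    function(idsTy) {
      alUp <- lapply(stepUnits[idsTy], function(u) u$up$alignment)
      alDn <- lapply(stepUnits[idsTy], function(u) u$down$alignment)
      list(step_up = friedmanStep(alUp),
           step_down = friedmanStep(alDn),
           adapt_up = friedmanStep(alUp, preOrdinals = 0:2,
                                   postOrdinals = 23:25),
           adapt_down = friedmanStep(alDn, preOrdinals = 0:2,
                                     postOrdinals = 23:25))
    })
  battery <- jsdBattery(triadsOnly, unitTypes = stepTypesOf,
                        alpha = config$alphas[1L])
  corr <- jsdCountCorrelation(triadsOnly)
  report$steps <- list(friedman = friedman, jsd = battery,
                       correlation = corr)

  ## stage 6: receptive fields (one demonstration sweep pair per type)
  rfTypes <- c("broad_monomodal", "mildly_inhibited")
  rf <- lapply(rfTypes, function(ty) {
    rc <- generateMovingObjectExperiment(arch[[ty]],
                                         sweep = list(start = 0, end = 100,
                                                      speed = 1),
                                         meanInterval = config$meanInterval,
                                         shape = config$shape)
    cr2 <- generateMovingObjectExperiment(arch[[ty]],
                                          sweep = list(start = 100, end = 0,
                                                       speed = 1),
                                          meanInterval = config$meanInterval,
                                          shape = config$shape)
    pRC <- positionRateProfile(rc$spikes, rc$eods, rc$trace)
    pCR <- positionRateProfile(cr2$spikes, cr2$eods, cr2$trace)
    list(profile_rc = pRC, profile_cr = pCR,
         contrast = directionContrast(pRC, pCR))
  })
  names(rf) <- rfTypes
  report$receptive_field <- rf

  if (!is.null(outDir)) .writeReportBundle(report, units, cr, outDir)
  report
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same units
#' (1 for identical partitions up to label permutation, about 0 at chance).
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sumIj <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expIdx <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expIdx) return(1)
  (sumIj - expIdx) / (maxIdx - expIdx)
}

.writeReportBundle <- function(report, units, clusterResult, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeEvents(unlist(lapply(units, function(u) list(u$eods, u$spikes)),
                     recursive = FALSE),
              file.path(outDir, "events.tsv"))
  lab <- clusterLabels(clusterResult)
  write.table(data.frame(unit_id = names(lab), cluster = lab),
              file.path(outDir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  curve <- dbCurve(clusterResult)
  write.table(data.frame(k = as.integer(names(curve)), db_index = curve),
              file.path(outDir, "db_curve.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeClusterNewick(clusterTree(clusterResult),
                     file.path(outDir, "dendrogram.nwk"))
  jsonlite::write_json(
    list(provenance = report$provenance,
         filter = report$filter,
         chosen_k = report$classification$chosen_k,
         ari = report$classification$ari,
         jsd_tests = report$steps$jsd$tests,
         jsd_divergences = report$steps$jsd$divergences),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(outDir)
}
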