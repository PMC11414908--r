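test_that("EOD trains are deterministic under a fixed seed and hit the mean interval", {
  t1 <- generateEODTrain(nEods = 2000, seed = 61)
  t2 <- generateEODTrain(nEods = 2000, seed = 61)
  expect_identical(eventTimes(t1), eventTimes(t2))
  big <- generateEODTrain(nEods = 12000, seed = 62)
  iv <- diff(eventTimes(big))
  se <- sd(iv) / sqrt(length(iv))
  expect_lt(abs(mean(iv) - 44.5), 3 * se)
  # degenerate duration: possibly empty train, no error
  tiny <- generateEODTrain(duration = 0.001, seed = 63)
  expect_lte(nEvents(tiny), 1L)
  expect_error(generateEODTrain(nEods = 10, duration = 1), "exactly one")
  expect_error(generateEODTrain(duration = -1), "positive")
})

test_that("spike generation respects silence, blanking, and determinism", {
  eods <- generateEODTrain(nEods = 800, seed = 64)
  silent <- unitArchetype("silent", modes = NULL, baselineRate = 0)
  expect_equal(nEvents(generateUnitSpikes(eods, silent, seed = 1)), 0L)
  # no spike within +/- 2.5 ms of any EOD, for every archetype
  for (a in defaultArchetypes()) {
    sp <- generateUnitSpikes(eods, a, seed = 65)
    et <- eventTimes(eods)
    st <- eventTimes(sp)
    gap <- vapply(st, function(s) min(abs(s - et)), numeric(1))
    expect_gt(min(gap), 2.5)
    expect_identical(eventTimes(generateUnitSpikes(eods, a, seed = 66)),
                     eventTimes(generateUnitSpikes(eods, a, seed = 66)))
  }
  expect_error(generateUnitSpikes(eods, silent, stimulus = 1:3), "length")
})

test_that("a single narrow mode lands its histogram peak at the mode latency", {
  a <- unitArchetype("one", modes = c(10, 0.5, 1))
  eods <- generateEODTrain(nEods = 3000, seed = 67)
  sp <- applyBlanking(generateUnitSpikes(eods, a), eods)
  h <- postEODHistogram(sp, eods)
  expect_equal(binCenters(h)[which.max(histValues(h))], 10)
  # Monte-Carlo check of the empirical histogram against the Gaussian mass
  gauss <- diff(pnorm(c(2.5, binCenters(h) + 0.5), 10, 0.5))
  expect_lt(0.5 * sum(abs(histValues(h) - gauss / sum(gauss))), 0.05)
})

test_that("step experiments provide 25 flanking EODs and honour protocol errors", {
  ex <- generateStepExperiment(defaultArchetypes()$bimodal,
                               stepProtocol(nTrials = 4), seed = 68)
  expect_length(ex$stepTimes, 4L)
  et <- eventTimes(ex$eods)
  for (s in ex$stepTimes) {
    i0 <- findInterval(s, et) + 1L
    expect_gte(i0 - 1L, 25L)
    expect_gte(length(et) - i0, 25L)
  }
  # stimulus levels alternate between exactly the two protocol levels
  expect_setequal(unique(ex$levels), c(1, 3))
  expect_error(generateStepExperiment(defaultArchetypes()$bimodal,
                                      stepProtocol(dutyShort = 0.5)),
               "25 flanking")
})

test_that("unit gain of 1 reduces the generator to a stationary EOD-locked process", {
  a <- defaultArchetypes()$bimodal
  a@countGainUp <- 1
  a@countGainDown <- 1
  ex <- generateStepExperiment(a, stepProtocol(nTrials = 24), seed = 69)
  al <- alignOrdinal(ex$spikes, ex$eods, ex$stepTimes)
  counts <- countsPerOrdinal(al)
  pre <- counts$mean[ordinalIndex(al) < 0]
  post <- counts$mean[ordinalIndex(al) >= 0]
  # flat ordinal profile: pre/post means equal within sampling error
  seDiff <- sqrt(var(pre) / length(pre) + var(post) / length(post))
  expect_lt(abs(mean(pre) - mean(post)), 4 * seDiff)
})

test_that("count gain drives a phasic, adapting step response", {
  # Monte-Carlo comparison of the ordinal count profile against the
  # generating gain x adaptation curve
  a <- defaultArchetypes()$bimodal     # gain up = 3, tau = 8
  reps <- lapply(1:40, function(i) {
    ex <- generateStepExperiment(a, stepProtocol(nTrials = 4),
                                 seed = 700 + i)
    al <- alignOrdinal(ex$spikes, ex$eods, ex$stepTimes)
    countsPerOrdinal(al)$mean
  })
  prof <- colMeans(do.call(rbind, reps))
  ords <- -25:25
  base <- mean(prof[ords < 0])
  relGain <- prof[ords >= 0] / base
  wantGain <- 1 + (a@countGainUp - 1) * exp(-(0:25) / a@adaptationTau)
  # truncation at 4 spikes/interval slightly compresses the peak
  expect_gt(relGain[1], 2)
  expect_lt(max(abs(relGain - wantGain)), 0.45)
  expect_lt(mean(relGain[24:26]), 1.45)   # adaptation back toward baseline
})

test_that("the population ledger matches the emitted spike trains", {
  ex <- generateStepExperiment(defaultArchetypes()$trimodal,
                               stepProtocol(nTrials = 3), seed = 71)
  # per-interval ledger counts equal direct interval counts of the train
  et <- eventTimes(ex$eods)
  st <- eventTimes(ex$spikes)
  direct <- tabulate(findInterval(st, et), nbins = length(et) - 1L)
  expect_equal(ex$truth$count, direct)
})

test_that("moving-object sweeps obey kinematics and the receptive-field profile", {
  a <- defaultArchetypes()$broad_monomodal
  ex <- generateMovingObjectExperiment(a, sweep = list(start = 0, end = 100,
                                                       speed = 1), seed = 72)
  expect_lte(max(eventTimes(ex$eods)), 100 * 1000)   # 100 mm at 1 mm/s = 100 s
  expect_equal(ex$direction, "rostral_to_caudal")
  expect_true(all(ex$positions >= 0 & ex$positions <= 100))
  # flat profile for a unit without receptive-field modulation
  flat <- a
  flat@rfProfile$ampExc <- 0
  flat@rfProfile$ampInh <- 0
  exF <- generateMovingObjectExperiment(flat, sweep = list(start = 0,
                                                           end = 100,
                                                           speed = 1),
                                        seed = 73)
  expect_true(all(abs(exF$gains - 1) < 1e-12))
  expect_error(generateMovingObjectExperiment(a, sweep = list(start = 5,
                                                              end = 5,
                                                              speed = 1)),
               "zero-length")
  expect_error(generateMovingObjectExperiment(a, sweep = list(start = 0,
                                                              end = 10,
                                                              speed = 0)),
               "speed")
})

test_that("population simulation is reproducible and labelled one-to-one", {
  p1 <- generatePopulation(nPerType = 2, nEods = 120, seed = 74)
  p2 <- generatePopulation(nPerType = 2, nEods = 120, seed = 74)
  expect_identical(lapply(p1$units, function(u) eventTimes(u$spikes)),
                   lapply(p2$units, function(u) eventTimes(u$spikes)))
  expect_equal(nrow(p1$truth), 12L)
  expect_identical(sort(unique(p1$truth$archetype)),
                   sort(names(defaultArchetypes())))
})
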