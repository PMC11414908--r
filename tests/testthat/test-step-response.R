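test_that("ordinal alignment applies the EOD_0 boundary convention", {
  et <- seq(0, by = 40, length.out = 60)
  eods <- EventSeries(et, "EOD")
  spikes <- EventSeries(et[30] + 10, "spike")
  # step exactly at an EOD time: that EOD is EOD_0
  al <- alignOrdinal(spikes, eods, stepTimes = et[30], nPre = 10, nPost = 10)
  expect_equal(unname(ordinalCounts(al)[1, "0"]), 1L)
  # step just after the same EOD: the next EOD becomes EOD_0
  al2 <- alignOrdinal(spikes, eods, stepTimes = et[30] + 0.01,
                      nPre = 10, nPost = 10)
  expect_equal(unname(ordinalCounts(al2)[1, "-1"]), 1L)
  # no spikes: all-empty latency lists
  al3 <- alignOrdinal(EventSeries(numeric(0), "spike"), eods,
                      stepTimes = et[30], nPre = 5, nPost = 5)
  expect_true(all(ordinalCounts(al3) == 0))
  expect_length(ordinalLatencies(al3)[[1]], 11L)
  # step near the recording edge is dropped with a warning
  expect_warning(al4 <- alignOrdinal(spikes, eods, stepTimes = c(et[2], et[30]),
                                     nPre = 10, nPost = 10), "dropped")
  expect_equal(nrow(ordinalCounts(al4)), 1L)
})

test_that("ordinal count matrices equal the generator's ledger", {
  ex <- generateStepExperiment(defaultArchetypes()$bimodal,
                               stepProtocol(nTrials = 5), seed = 81)
  al <- alignOrdinal(ex$spikes, ex$eods, ex$stepTimes)
  et <- eventTimes(ex$eods)
  for (tr in seq_along(ex$stepTimes)) {
    k <- findInterval(ex$stepTimes[tr], et)
    i0 <- if (k >= 1 && et[k] == ex$stepTimes[tr]) k else k + 1L
    want <- ex$truth$count[(i0 - 25):(i0 + 25)]
    expect_equal(unname(ordinalCounts(al)[tr, ]), want)
  }
  cp <- countsPerOrdinal(al)
  expect_equal(cp$total, colSums(ordinalCounts(al)))
  prof <- typeCountProfile(list(al, al))
  expect_equal(prof$median, unname(colMeans(ordinalCounts(al))))
})

test_that("single spike after EOD_0 yields an indicator count profile", {
  et <- seq(0, by = 40, length.out = 60)
  sp <- EventSeries(et[30] + 12.3, "spike")
  al <- alignOrdinal(sp, EventSeries(et, "EOD"), et[30], nPre = 5, nPost = 5)
  want <- rep(0L, 11)
  want[6] <- 1L
  expect_equal(unname(countsPerOrdinal(al)$total), want)
})

test_that("jsd satisfies its axioms and the entropy arithmetic oracle", {
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  # direct arithmetic: H(0.75, 0.25) - (1 + 0)/2
  want <- -(0.75 * log2(0.75) + 0.25 * log2(0.25)) - 0.5
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), want, tolerance = 1e-12)
  expect_error(jsd(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  expect_error(jsd(c(0.5, 0.5), c(0.5, 0.25, 0.25)), "equal length")
  set.seed(82)
  for (rep in 1:50) {
    m <- sample(2:12, 1)
    p <- runif(m); p <- p / sum(p)
    q <- runif(m); q <- q / sum(q)
    r <- runif(m); r <- r / sum(r)
    expect_equal(jsd(p, q), jsd(q, p))
    expect_gte(jsd(p, q), 0)
    expect_lte(jsd(p, q), 1)
    expect_equal(jsd(p, p), 0)
    # square root of the divergence behaves as a metric
    expect_lte(sqrt(jsd(p, r)), sqrt(jsd(p, q)) + sqrt(jsd(q, r)) + 1e-12)
  }
})

test_that("triad distributions pool the named ordinal ranges only", {
  et <- seq(0, by = 40, length.out = 120)
  eods <- EventSeries(et, "EOD")
  step <- et[60]
  # one spike in the pre triad (ordinal -2) and two in the post triad
  sp <- EventSeries(c(et[58] + 10.2, et[60] + 5.4, et[62] + 20.1), "spike")
  al <- alignOrdinal(sp, eods, step)
  tri <- triadDistributions(al)
  expect_equal(tri$pre$nSpikes, 1L)
  expect_equal(tri$post$nSpikes, 2L)
  expect_equal(tri$long_control$nSpikes, 0L)
  expect_true(anyNA(tri$long_control$prob))
  expect_equal(sum(tri$post$prob), 1)
  expect_equal(tri$post$meanCount, 2 / 3)
  expect_equal(tri$pre$counts[tri$pre$centers == 10], 1L)
})

test_that("replicated Friedman detects strong count steps and stays null-calibrated", {
  set.seed(83)
  # power at the stated 3-fold effect, 8 units
  hits <- replicate(60, {
    weak <- matrix(rpois(8 * 25, 1), 8)
    strong <- matrix(rpois(8 * 25, 3), 8)
    friedmanSteady(weak, strong)$p.value < 0.005
  })
  expect_gte(mean(hits), 0.95)
  # direction under a strong step effect, via alignments
  sb <- lapply(1:8, function(i) {
    ex <- generateStepExperiment(defaultArchetypes()$bimodal,
                                 stepProtocol(nTrials = 16), seed = 830 + i)
    alignOrdinal(ex$spikes, ex$eods, ex$stepTimes)
  })
  fs <- friedmanStep(sb)
  expect_lt(fs$p.value, 0.005)
  expect_gt(fs$medianPost, fs$medianPre)
})

test_that("the JSD battery separates timing effects from count effects", {
  arch <- defaultArchetypes()$bimodal
  # timing-shifted generator (count-invariant): battery significant in
  # both directions
  shifted <- arch
  shifted@timingShift <- 5
  shifted@countGainUp <- 1
  shifted@countGainDown <- 1
  set.seed(84)
  sbS <- stepBattery(shifted, nUnits = 8, nTrials = 24, jitter = FALSE)
  triS <- lapply(sbS, function(u) list(up = u$up$triads, down = u$down$triads))
  jbS <- jsdBattery(triS)
  expect_true(all(jbS$tests$p < 0.05))
  # count-only generator (gain 3, no shift): non-significant timing tests
  set.seed(85)
  sbC <- stepBattery(arch, nUnits = 8, nTrials = 16, jitter = FALSE)
  triC <- lapply(sbC, function(u) list(up = u$up$triads, down = u$down$triads))
  jbC <- jsdBattery(triC)
  expect_true(all(jbC$tests$p > 0.05, na.rm = TRUE))
  # a single unit: divergences reported, no test
  jb1 <- jsdBattery(triS[1])
  expect_equal(nrow(jb1$divergences), 1L)
  expect_true(all(is.na(jb1$tests$p)))
  expect_true(all(jb1$divergences[, -1] >= 0 & jb1$divergences[, -1] <= 1))
})

test_that("timing-shift power holds across all four studied types", {
  set.seed(86)
  allTri <- list()
  types <- character(0)
  for (ty in c("sharp_monomodal", "broad_monomodal", "mildly_inhibited",
               "bimodal")) {
    a <- defaultArchetypes()[[ty]]
    a@timingShift <- 5
    a@countGainUp <- 1
    a@countGainDown <- 1
    sb <- stepBattery(a, nUnits = 8, nTrials = 48, jitter = FALSE)
    tri <- lapply(sb, function(u) list(up = u$up$triads, down = u$down$triads))
    allTri <- c(allTri, tri)
    types <- c(types, setNames(rep(ty, length(tri)), names(tri)))
  }
  jb <- jsdBattery(allTri, unitTypes = types)
  expect_true(all(jb$tests$reject))
})

test_that("JSD-count correlations decouple and couple as designed", {
  arch <- defaultArchetypes()$bimodal
  # count-only modulation with fixed timing: low R^2
  set.seed(87)
  sb <- stepBattery(arch, nUnits = 6, nTrials = 16, jitter = FALSE)
  tri <- lapply(sb, function(u) list(up = u$up$triads, down = u$down$triads))
  corr <- jsdCountCorrelation(tri)
  expect_equal(nrow(corr), 6L)
  expect_lt(median(corr$r2_absdiff, na.rm = TRUE), 0.3)
  # coupled generator: a sustained count gain (negligible adaptation)
  # rides along with the timing shift, so count and timing change together
  coupled <- arch
  coupled@timingShift <- 6
  coupled@countGainDown <- 1
  coupled@adaptationTau <- 1e6
  set.seed(88)
  sbK <- stepBattery(coupled, nUnits = 6, nTrials = 24, jitter = FALSE)
  triK <- lapply(sbK, function(u) list(up = u$up$triads, down = u$down$triads))
  corrK <- jsdCountCorrelation(triK)
  expect_gt(median(corrK$r2_absdiff, na.rm = TRUE), 0.4)
  expect_gt(median(corrK$r2_absdiff, na.rm = TRUE),
            median(corr$r2_absdiff, na.rm = TRUE))
  # degenerate regressor: identical triads -> flagged
  degTri <- list(u1 = list(up = tri[[1]]$up, down = tri[[1]]$up))
  degTri$u1$down <- degTri$u1$up
  degTri$u1$up$pre <- degTri$u1$up$post <- degTri$u1$up$late
  degTri$u1$down$pre <- degTri$u1$down$post <- degTri$u1$down$late
  expect_true(jsdCountCorrelation(degTri)$flagged[1])
})
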