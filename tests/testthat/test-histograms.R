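test_that("cross-correlation histogram counts pairs by hand-checkable rules", {
  ed <- EventSeries(0, "EOD")
  # bins are centered on integer latencies: [9.5, 10.5) is the 10 ms bin
  sp <- EventSeries(c(9.7, 10.2), "spike")
  h <- crosscorrHistogram(sp, ed)
  expect_identical(histNormalization(h), "percent_per_eod")
  expect_equal(histValues(h)[binCenters(h) == 10], 200)  # 2 spikes / 1 EOD
  expect_equal(sum(histValues(h)), 200)
  # bins fully inside the blanking window are flagged
  expect_setequal(binCenters(h)[blankedBins(h)], -2:2)
})

test_that("blanked spikes leave the artifact bins empty", {
  ed <- generateEODTrain(nEods = 300, seed = 21)
  sp <- applyBlanking(generateUnitSpikes(ed, defaultArchetypes()$bimodal),
                      ed)
  h <- crosscorrHistogram(sp, ed)
  expect_true(all(histValues(h)[blankedBins(h)] == 0))
})

test_that("an EOD-independent Poisson train gives a flat cross-correlogram", {
  set.seed(22)
  nE <- 5000
  ed <- generateEODTrain(nEods = nE)
  span <- max(eventTimes(ed)) + 400
  rateMs <- 0.004                         # 4 spikes/s
  sp <- EventSeries(sort(runif(rpois(1, rateMs * span), 0, span)), "spike")
  h <- crosscorrHistogram(sp, ed)
  expected <- 100 * nEvents(sp) / span    # percent per EOD per 1 ms bin
  vals <- histValues(h)[-blankedBins(h)]
  # per-bin counts are ~ binomial; allow 5 sigma on each bin and 2% on mean
  sigma <- 100 * sqrt(rateMs / nE)
  expect_lt(max(abs(vals - expected)), 5 * sigma + 1e-9)
  expect_lt(abs(mean(vals) - expected) / expected, 0.02)
})

test_that("percent-per-EOD values are invariant to duplicating the recording", {
  u <- simUnit(defaultArchetypes()$trimodal, nEods = 200, seed = 23)
  off <- max(eventTimes(u$eods)) + 500
  ed2 <- EventSeries(c(eventTimes(u$eods), eventTimes(u$eods) + off), "EOD")
  sp2 <- EventSeries(c(eventTimes(u$spikes), eventTimes(u$spikes) + off),
                     "spike")
  h1 <- crosscorrHistogram(u$spikes, u$eods)
  h2 <- crosscorrHistogram(sp2, ed2)
  # doubling the data leaves per-EOD values nearly unchanged (edge windows
  # of the junction contribute a handful of extra pairs)
  expect_equal(histValues(h2), histValues(h1), tolerance = 0.05)
})

test_that("post-EOD histograms are unit-sum probability vectors on 3..40 ms bins", {
  u <- simUnit(defaultArchetypes()$bimodal, nEods = 400, seed = 24)
  h <- postEODHistogram(u$spikes, u$eods)
  expect_identical(histNormalization(h), "unit_sum")
  expect_equal(binCenters(h), 3:40)
  expect_length(histValues(h), 38L)
  expect_equal(sum(histValues(h)), 1, tolerance = 1e-12)
  expect_true(all(histValues(h) >= 0))
})

test_that("post-EOD histogram degenerate and invariance cases", {
  ed <- EventSeries(c(0, 44, 88), "EOD")
  # all spikes at one latency -> a single unit bin
  sp <- EventSeries(c(10.2, 44 + 10.2), "spike")
  h <- postEODHistogram(sp, ed)
  expect_equal(histValues(h)[binCenters(h) == 10], 1)
  expect_equal(sum(histValues(h) > 0), 1L)
  # scale invariance: interleaving a copy of every spike (+0.01 ms) leaves
  # the distribution essentially unchanged
  spD <- EventSeries(sort(c(eventTimes(sp), eventTimes(sp) + 0.01)), "spike")
  expect_equal(histValues(postEODHistogram(spD, ed)), histValues(h))
  # no spikes in the window -> explicit empty signal
  expect_null(postEODHistogram(EventSeries(c(1.0, 43.0), "spike"), ed))
})

test_that("simulated bimodal histograms match the generating mixture", {
  # Monte-Carlo oracle: empirical post-EOD histogram vs the analytic
  # mixture intensity of the generator, total-variation distance < 0.1
  a <- defaultArchetypes()$bimodal
  u <- simUnit(a, nEods = 4000, seed = 25)
  h <- postEODHistogram(u$spikes, u$eods)
  expect_gte(nSpikes(h), 1000)
  centers <- binCenters(h)
  m <- a@modes
  dens <- rowSums(vapply(seq_len(nrow(m)), function(i)
    m[i, "weight"] * dnorm(centers, m[i, "latency"], m[i, "sd"]),
    numeric(length(centers))))
  dens <- dens + a@baselineRate / 1000          # uniform floor per ms
  ih <- a@inhibition
  thin <- rep(1, length(centers))
  for (w in seq_len(nrow(ih)))
    thin[centers >= ih[w, "start"] & centers < ih[w, "end"]] <-
      1 - ih[w, "depth"]
  surv <- dens * thin                           # surviving primaries
  # doublet echo: a surviving primary at latency l spawns a partner at
  # l + isi with probability burst[1]; isi = 4 ms = 4 bins here
  b <- a@burst
  shiftBins <- as.integer(round(b[2L]))
  echo <- c(rep(0, shiftBins), surv)[seq_along(surv)] * b[1L]
  expectProb <- (surv + echo) / sum(surv + echo)
  tv <- 0.5 * sum(abs(histValues(h) - expectProb))
  expect_lt(tv, 0.1)
})

test_that("peri-EOD percentile profiles behave for 1, 2 and many units", {
  us <- lapply(1:10, function(i)
    simUnit(defaultArchetypes()$broad_monomodal, nEods = 300, seed = 30 + i))
  hs <- lapply(us, function(u) crosscorrHistogram(u$spikes, u$eods))
  p1 <- periEODProfile(hs[1])
  expect_equal(p1[, "p20"], p1[, "p50"])
  expect_equal(p1[, "p50"], p1[, "p80"])
  p2 <- periEODProfile(hs[1:2])
  mid <- (histValues(hs[[1]]) + histValues(hs[[2]])) / 2
  keep <- binCenters(hs[[1]]) >= -15 & binCenters(hs[[1]]) <= 40
  expect_equal(unname(p2[, "p50"]), mid[keep])
  pAll <- periEODProfile(hs)
  expect_true(all(pAll[, "p20"] <= pAll[, "p50"] + 1e-12))
  expect_true(all(pAll[, "p50"] <= pAll[, "p80"] + 1e-12))
  # 20/80 band captures the cohort's central histogram in most bins
  med <- apply(vapply(hs, function(h) histValues(h)[keep],
                      numeric(sum(keep))), 1L, median)
  inBand <- med >= pAll[, "p20"] - 1e-9 & med <= pAll[, "p80"] + 1e-9
  expect_gte(mean(inBand), 0.9)
  expect_error(periEODProfile(list(hs[[1]], postEODHistogram(us[[1]]$spikes,
                                                             us[[1]]$eods))),
               "common binning")
})
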