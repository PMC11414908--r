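mkHist <- function(p, centers = seq(3, length.out = length(p))) {
  new("PeriEODHistogram", binCenters = as.numeric(centers),
      values = p / sum(p), normalization = "unit_sum",
      window = c(2.5, max(centers) + 0.5), nEODs = 100L,
      nSpikes = 100L, blankedBins = integer(0))
}

test_that("histogram distances are Euclidean norms with hand arithmetic", {
  hs <- list(a = mkHist(c(1, 0)), b = mkHist(c(0, 1)), c = mkHist(c(1, 1)))
  dm <- as.matrix(histogramDistanceMatrix(hs))
  expect_equal(dm["a", "b"], sqrt(2))
  expect_equal(dm["a", "c"], sqrt(0.25 + 0.25))
  expect_equal(dm["a", "a"], 0)
  n <- 20
  hs2 <- lapply(seq_len(n), function(i) mkHist(runif(5) + 0.1))
  expect_length(histogramDistanceMatrix(hs2), n * (n - 1) / 2)
  hBad <- mkHist(c(1, 1))
  hBad@normalization <- "percent_per_eod"
  expect_error(histogramDistanceMatrix(list(hBad, mkHist(c(1, 0)))),
               "unit_sum")
})

test_that("Ward tree merges two units at their distance and separates triplets", {
  hs <- list(u1 = mkHist(c(1, 0, 0)), u2 = mkHist(c(0, 0, 1)))
  tree <- wardCluster(histogramDistanceMatrix(hs))
  expect_equal(tree$height, sqrt(2))
  set.seed(41)
  X <- rbind(matrix(rnorm(9, 0, 0.05), 3), matrix(rnorm(9, 5, 0.05), 3))
  tree2 <- hclust(dist(X), method = "ward.D2")
  expect_setequal(split(1:6, cutree(tree2, 2)), list(1:3, 4:6))
})

test_that("Ward linkage reproduces exhaustive minimum-variance agglomeration", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    X <- matrix(rnorm(n * 3), n)
    tree <- wardCluster(dist(X))
    oracle <- wardGreedyPartitions(X)
    for (k in 2:(n - 1)) {
      want <- canonicalPartition(oracle[[n - k]])
      expect_identical(cutreePartition(tree, k), want)
    }
  }
})

test_that("Davies-Bouldin index matches the direct formula on a 1-D example", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1, 1, 2, 2)
  # S1 = S2 = 0.5, M12 = 10 -> DB = (0.5 + 0.5) / 10 = 0.1
  expect_equal(packetcode:::.dbIndex(X, labels), 0.1)
  set.seed(43)
  X2 <- matrix(rnorm(40), ncol = 2)
  lab2 <- rep(1:4, each = 5)
  expect_equal(packetcode:::.dbIndex(X2, lab2), dbDirect(X2, lab2))
})

test_that("the DB curve finds the true k for well-separated clusters and flags degeneracy", {
  set.seed(44)
  X <- do.call(rbind, lapply(c(0, 10, 20, 30), function(mu)
    matrix(rnorm(20, mu, 0.2), ncol = 2)))
  hs <- lapply(seq_len(nrow(X)), function(i) {
    v <- abs(X[i, ]) + 0.01
    mkHist(v / sum(v))
  })
  tree <- hclust(dist(X), method = "ward.D2")
  curve <- daviesBouldinCurve(X, tree, kRange = 2:8)
  expect_equal(as.integer(names(which.min(curve))), 4L)
  # all points identical except noise: indices degenerate or flat
  X0 <- matrix(rnorm(20, 0, 1e-9), ncol = 2)
  tree0 <- hclust(dist(X0), method = "ward.D2")
  curve0 <- daviesBouldinCurve(X0, tree0, kRange = 2:6)
  expect_true(all(is.finite(curve0)))
})

test_that("k selection reads elbows on monotone curves and minima on V curves", {
  kinked <- setNames(c(10, 8, 6, 4, 2, 1.9, 1.85, 1.8), 2:9)
  expect_equal(selectKElbow(kinked), 6L)
  linear <- setNames(seq(10, 3, by = -1), 2:9)
  expect_warning(k <- selectKElbow(linear), "no elbow")
  expect_equal(k, 9L)
  vshape <- setNames(c(5, 4, 3, 1, 3.2, 4.1, 5.3), 2:8)
  expect_equal(selectKElbow(vshape), 5L)
})

test_that("pairwise KS battery handles identity, separation, and type-I error", {
  set.seed(45)
  same <- runif(200, 5, 20)
  early <- runif(200, 3, 10)
  late <- runif(200, 25, 39)
  res <- pairwiseKSTests(list(a = same, b = same, c = early, d = late))
  pr <- res$pairs
  expect_false(pr$sig_0.05[pr$unit_i == "a" & pr$unit_j == "b"])
  expect_true(all(unlist(pr[pr$unit_i == "c" & pr$unit_j == "d",
                            c("sig_0.05", "sig_0.01", "sig_0.001")])))
  # Holm monotonicity across alpha levels
  expect_true(all(!pr$sig_0.001 | pr$sig_0.01))
  expect_true(all(!pr$sig_0.01 | pr$sig_0.05))
  # type-I calibration of the raw (uncorrected) KS p-values
  rej <- mean(replicate(500, {
    x <- runif(60, 3, 30); y <- runif(60, 3, 30)
    suppressWarnings(ks.test(x, y))$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 2 * sqrt(0.05 * 0.95 / 500) + 0.015)
})

test_that("group comparison reproduces the hand-ranked Kruskal-Wallis statistic", {
  vals <- c(1, 3, 5, 2, 9, 11, 4, 12, 13, 6, 7, 8, 14, 15, 10)
  grp <- rep(c("g1", "g2", "g3"), each = 5)
  got <- compareGroups(vals, grp)
  # independent hand computation: H = 12/(N(N+1)) * sum R_j^2/n_j - 3(N+1)
  R <- tapply(rank(vals), grp, sum)
  H <- 12 / (15 * 16) * sum(R^2 / 5) - 3 * 16
  expect_equal(got$omnibus$statistic, H)
  expect_equal(got$omnibus$df, 2)
  # strong separation: omnibus and all pairwise significant
  set.seed(46)
  vals2 <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1), rnorm(8, 20, 0.1))
  got2 <- compareGroups(vals2, grp <- rep(c("a", "b", "c"), each = 8))
  expect_lt(got2$omnibus$p.value, 0.001)
  expect_true(all(got2$pairwise$reject))
  expect_warning(compareGroups(c(vals2, 1), c(grp, "lonely")), "excluding")
})

test_that("cluster labels are invariant to unit order and recover the archetypes", {
  set.seed(47)
  pop <- generatePopulation(nPerType = 6, nEods = 500, seed = 47)
  for (id in names(pop$units))
    pop$units[[id]]$spikes <- applyBlanking(pop$units[[id]]$spikes,
                                            pop$units[[id]]$eods)
  post <- Filter(Negate(is.null), lapply(pop$units, function(u)
    postEODHistogram(u$spikes, u$eods)))
  cr1 <- classifyUnits(post, k = 6)
  perm <- sample(length(post))
  cr2 <- classifyUnits(post[perm], k = 6)
  l1 <- clusterLabels(cr1)
  l2 <- clusterLabels(cr2)[names(l1)]
  expect_equal(adjustedRandIndex(l1, l2), 1)
  truth <- pop$truth$archetype[match(names(l1), pop$truth$unit_id)]
  expect_gte(adjustedRandIndex(l1, truth), 0.9)
})
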