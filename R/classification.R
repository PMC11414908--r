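#' Euclidean distance matrix between post-EOD histograms
#'
#' Pairwise Euclidean distances between the unit-sum post-EOD histograms of
#' all units (the 2.5--40 ms bin vectors), the dissimilarity on which the
#' hierarchical classification is built.
#'
#' @param histograms named list of \linkS4class{PeriEODHistogram} in
#'   `unit_sum` normalization with identical binning.
#' @return A [stats::dist] object (n(n-1)/2 condensed entries).
#' @export
histogramDistanceMatrix <- function(histograms) {
  if (length(histograms) < 2L) stop("need at least 2 units")
  norm <- vapply(histograms, histNormalization, "")
  if (!all(norm == "unit_sum"))
    stop("histograms must be unit_sum normalized")
  ctr <- binCenters(histograms[[1L]])
  same <- vapply(histograms, function(h)
    length(binCenters(h)) == length(ctr) && all(binCenters(h) == ctr),
    logical(1))
  if (!all(same)) stop("histograms must share a common binning")
  X <- t(vapply(histograms, histValues, numeric(length(ctr))))
  dist(X)
}

#' Ward linkage tree
#'
#' Agglomerative minimum-within-cluster-variance (Ward) clustering of the
#' Euclidean histogram distances, via [stats::hclust] with the `"ward.D2"`
#' criterion (the Ward objective for Euclidean input distances).
#'
#' @param dm a [stats::dist] object.
#' @return An [stats::hclust] tree.
#' @export
wardCluster <- function(dm) {
  if (!inherits(dm, "dist")) stop("dm must be a 'dist' object")
  if (attr(dm, "Size") < 2L) stop("need at least 2 units")
  hclust(dm, method = "ward.D2")
}

## Davies-Bouldin index of one partition.
## variant "centroid": the textbook index -- per-cluster dispersion S_i =
##   mean Euclidean distance to the centroid, separation M_ij = centroid
##   distance, DB = mean_i max_{j != i} (S_i + S_j) / M_ij (lower = better).
## variant "extrema": the looser ratio of the minimal inter-cluster centroid
##   distance to the maximal intra-cluster pairwise distance (higher =
##   better); provided because published descriptions sometimes use it.
.dbIndex <- function(X, labels, variant = "centroid") {
  ks <- sort(unique(labels))
  cent <- do.call(rbind, lapply(ks, function(k)
    colMeans(X[labels == k, , drop = FALSE])))
  M <- as.matrix(dist(cent))
  if (variant == "centroid") {
    S <- vapply(seq_along(ks), function(i) {
      Xi <- X[labels == ks[i], , drop = FALSE]
      mean(sqrt(rowSums((Xi - rep(cent[i, ], each = nrow(Xi)))^2)))
    }, numeric(1))
    R <- outer(S, S, `+`) / M
    diag(R) <- NA
    if (all(!is.finite(R[upper.tri(R) | lower.tri(R)]))) return(NA_real_)
    mean(apply(R, 1L, max, na.rm = TRUE))
  } else {
    intra <- vapply(ks, function(k) {
      Xi <- X[labels == k, , drop = FALSE]
      if (nrow(Xi) < 2L) 0 else max(dist(Xi))
    }, numeric(1))
    mx <- max(intra)
    if (mx == 0) return(NA_real_)
    min(M[upper.tri(M)]) / mx
  }
}

#' Davies-Bouldin curve over candidate cluster counts
#'
#' Cuts the Ward tree at every k in `kRange` and computes the
#' Davies-Bouldin index of the resulting partition in histogram space.
#'
#' @param histograms the histogram list used to build the tree (or a numeric
#'   units x bins matrix).
#' @param tree the [stats::hclust] tree from [wardCluster()].
#' @param kRange candidate cluster counts (default 2..12).
#' @param variant `"centroid"` (textbook, default) or `"extrema"`; see
#'   Details in [selectKElbow()].
#' @return Named numeric vector, one index per k (`NA` where undefined,
#'   e.g. all-singleton partitions).
#' @export
daviesBouldinCurve <- function(histograms, tree, kRange = 2:12,
                               variant = c("centroid", "extrema")) {
  variant <- match.arg(variant)
  X <- if (is.matrix(histograms)) histograms
       else t(vapply(histograms, histValues,
                     numeric(length(binCenters(histograms[[1L]])))))
  n <- nrow(X)
  kRange <- kRange[kRange >= 2 & kRange <= n]
  if (!length(kRange)) stop("kRange outside the attainable cluster counts")
  vals <- vapply(kRange, function(k) {
    labels <- cutree(tree, k = k)
    if (all(tabulate(labels) <= 1L)) return(NA_real_)
    .dbIndex(X, labels, variant)
  }, numeric(1))
  names(vals) <- kRange
  vals
}

#' Select the cluster count from the Davies-Bouldin curve
#'
#' Two regimes are handled.  A monotone non-increasing ("hyperbolic")
#' curve -- the shape the extrema-ratio variant produces when clusters keep
#' improving with k -- is read through its elbow, the maximal discrete
#' second difference `db(k+1) - 2 db(k) + db(k-1)`; a monotone curve
#' without curvature yields a warning and the k at the curve minimum.  The
#' textbook centroid index instead penalizes over-partitioning, so its
#' curve is V-shaped with an interior optimum; in that regime the index is
#' read the canonical way, at its minimum.
#'
#' @param dbCurve named numeric from [daviesBouldinCurve()].
#' @return Integer, the selected k.
#' @export
selectKElbow <- function(dbCurve) {
  dbCurve <- dbCurve[is.finite(dbCurve)]
  if (length(dbCurve) < 4L) stop("need the index over at least 4 k values")
  ks <- as.integer(names(dbCurve))
  if (any(diff(ks) != 1L)) stop("dbCurve must cover consecutive k")
  tol <- 1e-9 + 1e-6 * diff(range(dbCurve))
  if (any(diff(dbCurve) > tol))               # interior optimum: V regime
    return(ks[which.min(dbCurve)])
  d2 <- dbCurve[-c(1L, length(dbCurve))]
  d2[] <- dbCurve[-(1:2)] - 2 * dbCurve[-c(1L, length(dbCurve))] +
    dbCurve[-c(length(dbCurve) - 1L, length(dbCurve))]
  if (max(d2) <= tol) {
    warning("Davies-Bouldin curve shows no elbow; returning the curve minimum")
    return(ks[which.min(dbCurve)])
  }
  ks[-c(1L, length(ks))][which.max(d2)]
}

#' Classify units from their post-EOD histograms
#'
#' Convenience wrapper running the full classification: distance matrix,
#' Ward tree, Davies-Bouldin curve, elbow (or manual) selection of k, labels
#' and per-cluster percentile profiles.
#'
#' @param postHists named list of unit-sum \linkS4class{PeriEODHistogram}.
#' @param profileHists optional histogram list (e.g. percent-per-EOD
#'   peri-EOD histograms over -15..40 ms) used for the cluster profiles;
#'   defaults to `postHists`.
#' @param kRange candidate cluster counts.
#' @param k `"auto"` for elbow selection or an integer override.
#' @param variant Davies-Bouldin variant, see [daviesBouldinCurve()].
#' @return A \linkS4class{ClusterResult}.
#' @export
classifyUnits <- function(postHists, profileHists = postHists,
                          kRange = 2:12, k = "auto",
                          variant = c("centroid", "extrema")) {
  variant <- match.arg(variant)
  dm <- histogramDistanceMatrix(postHists)
  tree <- wardCluster(dm)
  curve <- daviesBouldinCurve(postHists, tree, kRange, variant)
  if (identical(k, "auto")) {
    chosen <- selectKElbow(curve)
    sel <- "elbow"
  } else {
    chosen <- as.integer(k)
    sel <- "manual"
  }
  labels <- cutree(tree, k = chosen)
  names(labels) <- names(postHists)
  profiles <- lapply(seq_len(chosen), function(cl)
    periEODProfile(profileHists[labels == cl],
                   window = range(binCenters(profileHists[[1L]]))))
  new("ClusterResult", tree = tree, dbCurve = curve,
      chosenK = as.integer(chosen), labels = labels, profiles = profiles,
      kSelection = sel)
}

#' Pairwise two-sample Kolmogorov-Smirnov tests between units
#'
#' Contrasts the raw post-EOD spike-latency samples (restricted to the
#' 2.5--40 ms window) of every pair of units with the two-sample KS test and
#' applies the Holm-Bonferroni step-down correction across all pairs; the
#' fraction of significantly different pairs is reported at each alpha.
#'
#' @param samples named list of numeric latency vectors (ms), one per unit.
#' @param alphas significance levels (default 0.05, 0.01, 0.001).
#' @param window latency window; samples are clipped to it.
#' @return A list: `pairs` (data frame `unit_i`, `unit_j`, `p`, `p_holm`,
#'   one logical column per alpha), `fractionSignificant` (named numeric),
#'   `skipped` (pairs with degenerate samples).
#' @export
pairwiseKSTests <- function(samples, alphas = c(0.05, 0.01, 0.001),
                            window = c(2.5, 40)) {
  samples <- lapply(samples, function(s) s[s >= window[1L] & s < window[2L]])
  ids <- names(samples)
  if (is.null(ids)) ids <- as.character(seq_along(samples))
  cmb <- combn(length(samples), 2L)
  usable <- vapply(samples, function(s) length(s) >= 2L, logical(1))
  okPair <- usable[cmb[1L, ]] & usable[cmb[2L, ]]
  p <- rep(NA_real_, ncol(cmb))
  p[okPair] <- vapply(which(okPair), function(j)
    suppressWarnings(ks.test(samples[[cmb[1L, j]]],
                             samples[[cmb[2L, j]]]))$p.value, numeric(1))
  pHolm <- rep(NA_real_, length(p))
  pHolm[okPair] <- p.adjust(p[okPair], method = "holm")
  out <- data.frame(unit_i = ids[cmb[1L, ]], unit_j = ids[cmb[2L, ]],
                    p = p, p_holm = pHolm)
  for (a in alphas)
    out[[sprintf("sig_%g", a)]] <- !is.na(pHolm) & pHolm < a
  frac <- vapply(alphas, function(a)
    mean(out[[sprintf("sig_%g", a)]][okPair]), numeric(1))
  names(frac) <- sprintf("alpha_%g", alphas)
  list(pairs = out, fractionSignificant = frac,
       skipped = out[!okPair, c("unit_i", "unit_j")])
}

#' Omnibus and pairwise comparison of a unit property across groups
#'
#' Kruskal-Wallis analysis of variance of a per-unit scalar (recording
#' depth, mean latency, spikes/EOD, ...) across unit types, followed by all
#' pairwise Wilcoxon rank-sum tests with Holm-Bonferroni correction.
#'
#' @param values named numeric, one scalar per unit.
#' @param groups factor or character, group of each unit.
#' @param alpha significance level for the corrected pairwise decisions.
#' @return A list: `omnibus` (chi-squared, df, p), `pairwise` (data frame
#'   with `group_i`, `group_j`, `p`, `p_holm`, `reject`), `excluded`
#'   (groups with fewer than 2 members, dropped with a warning).
#' @export
compareGroups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2L]
  if (length(excluded)) {
    warning("excluding group(s) with < 2 members: ",
            paste(excluded, collapse = ", "))
    keep <- !groups %in% excluded
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L) stop("need at least 2 usable groups")
  kw <- kruskal.test(values, factor(groups))
  gs <- sort(unique(groups))
  cmb <- combn(length(gs), 2L)
  p <- vapply(seq_len(ncol(cmb)), function(j)
    suppressWarnings(wilcox.test(values[groups == gs[cmb[1L, j]]],
                                 values[groups == gs[cmb[2L, j]]]))$p.value,
    numeric(1))
  hb <- holmBonferroni(p, alpha)
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value),
       pairwise = data.frame(group_i = gs[cmb[1L, ]], group_j = gs[cmb[2L, ]],
                             p = p, p_holm = hb$adjusted,
                             reject = hb$reject),
       excluded = excluded)
}

#' Write a Ward tree as Newick text
#'
#' @param tree an [stats::hclust] object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeClusterNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
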