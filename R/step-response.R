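#' Align spikes to ordinal EODs around stimulus steps
#'
#' For every stimulus step, EOD_0 is the first EOD emitted at or after the
#' step time, ordinals run from `-nPre` to `+nPost`, and the spikes of the
#' inter-EOD interval following each ordinal EOD are collected as latencies
#' to that (preceding) EOD.  Steps without the full complement of flanking
#' EODs are dropped with a warning.
#'
#' @param spikes,eods \linkS4class{EventSeries} (blanked spikes).
#' @param stepTimes numeric step times (ms).
#' @param nPre,nPost flanking EOD counts (defaults 25).
#' @param unitId label stored in the alignment.
#' @return An \linkS4class{OrdinalAlignment}.
#' @export
alignOrdinal <- function(spikes, eods, stepTimes, nPre = 25, nPost = 25,
                         unitId = NA_character_) {
  stopifnot(is(spikes, "EventSeries"), is(eods, "EventSeries"))
  et <- eventTimes(eods)
  st <- eventTimes(spikes)
  ords <- seq.int(-nPre, nPost)
  lat <- list()
  cnt <- NULL
  dropped <- integer(0)
  for (s in seq_along(stepTimes)) {
    k <- findInterval(stepTimes[s], et)
    i0 <- if (k >= 1L && et[k] == stepTimes[s]) k else k + 1L
    if (i0 - nPre < 1L || i0 + nPost + 1L > length(et)) {
      dropped <- c(dropped, s)
      next
    }
    trial <- vector("list", length(ords))
    for (j in seq_along(ords)) {
      a <- et[i0 + ords[j]]
      b <- et[i0 + ords[j] + 1L]
      i1 <- findInterval(a, st)
      i2 <- findInterval(b, st, left.open = TRUE)
      trial[[j]] <- if (i2 > i1) st[(i1 + 1L):i2] - a else numeric(0)
    }
    lat[[length(lat) + 1L]] <- trial
    cnt <- rbind(cnt, lengths(trial))
  }
  if (length(dropped))
    warning(sprintf("%d step(s) too close to the recording edge dropped",
                    length(dropped)))
  if (is.null(cnt))
    cnt <- matrix(integer(0), 0, length(ords))
  colnames(cnt) <- ords
  new("OrdinalAlignment", ordinals = as.integer(ords), latencies = lat,
      counts = cnt, unitId = as.character(unitId),
      droppedTrials = as.integer(dropped))
}

#' Spike counts per ordinal EOD
#'
#' Summed and per-trial spike counts for every ordinal EOD of an alignment.
#'
#' @param alignment an \linkS4class{OrdinalAlignment}.
#' @return A list: `ordinals`, `total` (summed over trials), `mean`, `sd`
#'   (across trials).
#' @export
countsPerOrdinal <- function(alignment) {
  cnt <- ordinalCounts(alignment)
  list(ordinals = ordinalIndex(alignment),
       total = colSums(cnt),
       mean = colMeans(cnt),
       sd = apply(cnt, 2L, sd))
}

#' Per-type count profile across units
#'
#' Median and 20--80 percentile band of the per-unit mean counts per
#' ordinal EOD, across the units of one type.
#'
#' @param alignments list of \linkS4class{OrdinalAlignment} (one per unit).
#' @return A data frame: `ordinal`, `median`, `p20`, `p80`.
#' @export
typeCountProfile <- function(alignments) {
  m <- vapply(alignments, function(a) colMeans(ordinalCounts(a)),
              numeric(length(ordinalIndex(alignments[[1L]]))))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(alignments))
  data.frame(ordinal = ordinalIndex(alignments[[1L]]),
             median = apply(m, 1L, median),
             p20 = apply(m, 1L, quantile, probs = 0.2, names = FALSE),
             p80 = apply(m, 1L, quantile, probs = 0.8, names = FALSE))
}

#' Default triad definitions
#'
#' The named ordinal ranges pooled into spike-timing distributions:
#' `long_control` (EOD_-25..EOD_-4), `pre` (EOD_-3..EOD_-1), `post`
#' (EOD_0..EOD_2), `late` (EOD_23..EOD_25).
#'
#' @return Named list of integer vectors.
#' @export
defaultTriads <- function() {
  list(long_control = -25:-4, pre = -3:-1, post = 0:2, late = 23:25)
}

#' Triad-pooled spike-timing distributions
#'
#' Pools the latencies of the named ordinal ranges over all trials and bins
#' them into unit-sum histograms over the post-EOD window (1 ms bins,
#' 2.5--40 ms), together with the mean spike count per EOD of each triad.
#'
#' @param alignment an \linkS4class{OrdinalAlignment}.
#' @param triads named list of ordinal ranges (default [defaultTriads()]).
#' @param window latency window (ms).
#' @param binWidth bin width (ms).
#' @return Named list; each element holds `prob` (probability vector, `NA`
#'   when the triad is empty), `nSpikes`, `meanCount` (spikes/EOD) and
#'   `centers`.
#' @export
triadDistributions <- function(alignment, triads = defaultTriads(),
                               window = c(2.5, 40), binWidth = 1) {
  ords <- ordinalIndex(alignment)
  kmin <- ceiling(window[1L] / binWidth - 0.5 + 1e-9)
  kmax <- floor(window[2L] / binWidth + 0.5 - 1e-9)
  centers <- seq(kmin, kmax) * binWidth
  nTrials <- length(ordinalLatencies(alignment))
  lapply(triads, function(rng) {
    idx <- match(rng, ords)
    if (anyNA(idx)) stop("triad ordinals outside the alignment range")
    lats <- unlist(lapply(ordinalLatencies(alignment),
                          function(tr) unlist(tr[idx], use.names = FALSE)),
                   use.names = FALSE)
    lats <- lats[lats >= window[1L] & lats < window[2L]]
    nEodSlots <- length(rng) * nTrials
    if (!length(lats))
      return(list(prob = rep(NA_real_, length(centers)),
                  counts = integer(length(centers)), nSpikes = 0L,
                  meanCount = 0, centers = centers))
    b <- floor(lats / binWidth + 0.5) - kmin + 1L
    cnt <- tabulate(b, nbins = length(centers))
    list(prob = cnt / sum(cnt), counts = cnt, nSpikes = length(lats),
         meanCount = length(lats) / nEodSlots, centers = centers)
  })
}

#' Friedman contrast of steady-state counts at two stimulus levels
#'
#' Replicated Friedman test (blocks = units, treatments = weak vs strong,
#' replicates = the counts evoked by the 25 EODs preceding a step at each
#' level) for a systematic steady-state difference in spikes per EOD.
#'
#' @param weak,strong numeric matrices units x replicates of spike counts
#'   (same shape).
#' @param ... passed to [friedmanReplicated()].
#' @return See [friedmanReplicated()].
#' @export
friedmanSteady <- function(weak, strong, ...) {
  stopifnot(is.matrix(weak), is.matrix(strong), all(dim(weak) == dim(strong)))
  x <- array(c(weak, strong), c(nrow(weak), ncol(weak), 2L))
  x <- aperm(x, c(1L, 3L, 2L))          # blocks x treatments x replicates
  friedmanReplicated(x, ...)
}

#' Friedman contrast of counts across a stimulus step
#'
#' Replicated Friedman test with 3 replicates: for every unit the mean
#' spike count per EOD (across trials) at the three ordinals before the
#' step is contrasted with the three ordinals after it.  The same routine
#' serves the adaptation contrast (immediately-post vs late triad at the
#' same stimulus level).
#'
#' @param alignments list of \linkS4class{OrdinalAlignment}, one per unit.
#' @param preOrdinals,postOrdinals ordinal ranges (defaults -3..-1, 0..2).
#' @param ... passed to [friedmanReplicated()].
#' @return As [friedmanReplicated()], plus `medianPre` and `medianPost`
#'   (medians across units of the per-unit mean counts).
#' @export
friedmanStep <- function(alignments, preOrdinals = -3:-1, postOrdinals = 0:2,
                         ...) {
  if (length(alignments) < 2L) stop("need at least 2 units")
  getMeans <- function(a, rng) {
    idx <- match(rng, ordinalIndex(a))
    if (anyNA(idx)) stop("ordinals outside the alignment range")
    colMeans(ordinalCounts(a)[, idx, drop = FALSE])
  }
  pre <- t(vapply(alignments, getMeans, numeric(length(preOrdinals)),
                  rng = preOrdinals))
  post <- t(vapply(alignments, getMeans, numeric(length(postOrdinals)),
                   rng = postOrdinals))
  x <- array(c(pre, post), c(nrow(pre), ncol(pre), 2L))
  x <- aperm(x, c(1L, 3L, 2L))
  out <- friedmanReplicated(x, ...)
  out$medianPre <- median(rowMeans(pre))
  out$medianPost <- median(rowMeans(post))
  out
}

#' Jensen-Shannon divergence between two spike-timing distributions
#'
#' `JSD(p, q) = H((p + q) / 2) - (H(p) + H(q)) / 2` with base-2 entropies
#' (`0 log 0 = 0`), i.e. the mutual information between a fair binary label
#' and the mixture of the two distributions.  Symmetric, non-negative, at
#' most 1 bit (attained on disjoint supports).
#'
#' @param p,q probability vectors of equal length (bins may be zero; no
#'   pseudocounts are applied).
#' @return Divergence in bits.
#' @examples
#' jsd(c(0.5, 0.5), c(1, 0))   # about 0.3113
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (anyNA(p) || anyNA(q) || any(p < 0) || any(q < 0))
    stop("inputs must be non-negative probability vectors")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must sum to 1")
  H <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  max(H((p + q) / 2) - (H(p) + H(q)) / 2, 0)
}

## subsample a binned count vector to n spikes (without replacement)
.rarefyCounts <- function(cnt, n) {
  if (sum(cnt) <= n) return(cnt)
  tabulate(sample(rep.int(seq_along(cnt), cnt))[seq_len(n)], length(cnt))
}

## divergence between two triads, with all samples subsampled to nstar
## spikes and averaged over nResample draws; equalizing the sample sizes
## equalizes the upward small-sample bias of the plug-in divergence, so
## that paired contrasts of divergences are unbiased under the timing null
.jsdEqualized <- function(t1, t2, nstar, nResample = 20) {
  mean(vapply(seq_len(nResample), function(s) {
    a <- .rarefyCounts(t1$counts, nstar)
    b <- .rarefyCounts(t2$counts, nstar)
    jsd(a / sum(a), b / sum(b))
  }, numeric(1)))
}

#' Jensen-Shannon divergence battery over step-experiment triads
#'
#' For every unit the seven divergences of the standard battery are
#' computed: (a) long-control up vs long-control down, (b) pre vs
#' long-control (up), (c) pre vs long-control (down), (d) pre vs post (up),
#' (e) pre vs post (down), (f) post vs late (up), (g) post vs late (down).
#' Per unit type and step direction, a one-sided sign-rank test evaluates
#' whether the step adds timing information, i.e. whether
#' `JSD(pre, post) > JSD(long_control, pre)` across units; p-values are
#' Holm-corrected over all type x direction combinations.
#'
#' The plug-in divergence between binned samples is biased upward, the more
#' so the fewer the spikes; the triad pools differ widely in size (the long
#' control spans 22 ordinals, the triads 3, and the count gain scales the
#' post pool), which would bias the paired contrast.  With
#' `equalize = TRUE` (default) every triad of a unit is therefore
#' subsampled to the unit's smallest triad count (averaging over
#' `nResample` draws, consuming the RNG), so compared divergences carry
#' equal bias.
#'
#' @param unitTriads named list, one element per unit, each a list with
#'   `up` and `down` triad sets from [triadDistributions()].
#' @param unitTypes optional named character vector of unit types; when
#'   missing all units form one group.
#' @param alpha significance level for the Holm-corrected decisions.
#' @param equalize equalize triad sample sizes by rarefaction?
#' @param nResample subsample draws per divergence when equalizing.
#' @return A list: `divergences` (data frame, one row per unit, columns
#'   a..g), `tests` (data frame per type x direction with `n`, `p`,
#'   `p_holm`, `reject`), `excluded` (units with empty triads).
#' @export
jsdBattery <- function(unitTriads, unitTypes = NULL, alpha = 0.05,
                       equalize = TRUE, nResample = 20) {
  ids <- names(unitTriads)
  ok <- vapply(unitTriads, function(u)
    !anyNA(c(u$up$long_control$prob[1L], u$up$pre$prob[1L],
             u$up$post$prob[1L], u$up$late$prob[1L],
             u$down$long_control$prob[1L], u$down$pre$prob[1L],
             u$down$post$prob[1L], u$down$late$prob[1L])), logical(1))
  excluded <- ids[!ok]
  unitTriads <- unitTriads[ok]
  ids <- ids[ok]
  oneUnit <- function(u) {
    tri <- list(cu = u$up$long_control, cd = u$down$long_control,
                pu = u$up$pre, pd = u$down$pre,
                ou = u$up$post, od = u$down$post,
                lu = u$up$late, ld = u$down$late)
    if (equalize) {
      # equalization is per step direction, so that the paired contrast
      # d > b (resp. e > c) compares divergences of identical sample sizes
      nUp <- min(vapply(tri[c("cu", "pu", "ou", "lu")], `[[`, integer(1),
                        "nSpikes"))
      nDn <- min(vapply(tri[c("cd", "pd", "od", "ld")], `[[`, integer(1),
                        "nSpikes"))
      dv <- function(x, y, nstar) .jsdEqualized(tri[[x]], tri[[y]], nstar,
                                                nResample)
      c(a = dv("cu", "cd", min(tri$cu$nSpikes, tri$cd$nSpikes)),
        b = dv("pu", "cu", nUp), c = dv("pd", "cd", nDn),
        d = dv("pu", "ou", nUp), e = dv("pd", "od", nDn),
        f = dv("ou", "lu", nUp), g = dv("od", "ld", nDn))
    } else {
      dvRaw <- function(x, y) jsd(tri[[x]]$prob, tri[[y]]$prob)
      c(a = dvRaw("cu", "cd"), b = dvRaw("pu", "cu"), c = dvRaw("pd", "cd"),
        d = dvRaw("pu", "ou"), e = dvRaw("pd", "od"), f = dvRaw("ou", "lu"),
        g = dvRaw("od", "ld"))
    }
  }
  div <- t(vapply(unitTriads, oneUnit, numeric(7)))
  divergences <- data.frame(unit_id = ids, div, row.names = NULL)
  if (is.null(unitTypes)) unitTypes <- setNames(rep("all", length(ids)), ids)
  types <- unique(unitTypes[ids])
  rows <- list()
  for (ty in types) {
    sel <- ids[unitTypes[ids] == ty]
    for (dir in c("up", "down")) {
      stepCol <- if (dir == "up") "d" else "e"
      ctrlCol <- if (dir == "up") "b" else "c"
      x <- div[sel, stepCol, drop = TRUE]
      y <- div[sel, ctrlCol, drop = TRUE]
      p <- if (length(sel) >= 2L)
        signrankOneSided(x, y, alternative = "greater")$p.value
      else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(type = ty, direction = dir, n = length(sel), p = p)
    }
  }
  tests <- do.call(rbind, rows)
  okP <- !is.na(tests$p)
  tests$p_holm <- NA_real_
  tests$reject <- NA
  if (any(okP)) {
    hb <- holmBonferroni(tests$p[okP], alpha)
    tests$p_holm[okP] <- hb$adjusted
    tests$reject[okP] <- hb$reject
  }
  list(divergences = divergences, tests = tests, excluded = excluded)
}

#' Correlation between timing divergence and spike-count change
#'
#' For every unit, the 15 Jensen-Shannon divergences between the six
#' direction-specific triads (pre, post, late, for upward and downward
#' steps) are correlated with the absolute difference and with the ratio of
#' the corresponding mean spike counts.  Low coefficients of determination
#' indicate that spike timing and spike count carry complementary
#' information.
#'
#' @param unitTriads as in [jsdBattery()].
#' @param equalize,nResample see [jsdBattery()].
#' @return A data frame, one row per unit: `r_absdiff`, `r2_absdiff`,
#'   `p_absdiff`, `r_ratio`, `r2_ratio`, `p_ratio`, `flagged` (zero-variance
#'   regressor or empty triads).
#' @export
jsdCountCorrelation <- function(unitTriads, equalize = TRUE, nResample = 20) {
  rows <- lapply(names(unitTriads), function(id) {
    u <- unitTriads[[id]]
    tri <- list(u$up$pre, u$up$post, u$up$late,
                u$down$pre, u$down$post, u$down$late)
    if (any(vapply(tri, function(t) anyNA(t$prob[1L]), logical(1))))
      return(data.frame(unit_id = id, r_absdiff = NA, r2_absdiff = NA,
                        p_absdiff = NA, r_ratio = NA, r2_ratio = NA,
                        p_ratio = NA, flagged = TRUE))
    cmb <- combn(6L, 2L)
    d <- if (equalize) {
      nstar <- min(vapply(tri, `[[`, integer(1), "nSpikes"))
      apply(cmb, 2L, function(ij)
        .jsdEqualized(tri[[ij[1L]]], tri[[ij[2L]]], nstar, nResample))
    } else {
      apply(cmb, 2L, function(ij) jsd(tri[[ij[1L]]]$prob,
                                      tri[[ij[2L]]]$prob))
    }
    cts <- vapply(tri, `[[`, numeric(1), "meanCount")
    absdiff <- apply(cmb, 2L, function(ij) abs(cts[ij[1L]] - cts[ij[2L]]))
    ratio <- apply(cmb, 2L, function(ij) {
      lohi <- range(cts[ij])
      if (lohi[1L] <= 0) NA_real_ else lohi[2L] / lohi[1L]
    })
    res <- function(x) {
      okf <- is.finite(x) & is.finite(d)
      if (sum(okf) < 3 || sd(x[okf]) == 0 || sd(d[okf]) == 0)
        return(list(r = NA_real_, r2 = NA_real_, p.value = NA_real_,
                    flagged = TRUE))
      pearsonWithR2(x[okf], d[okf])
    }
    ra <- res(absdiff); rr <- res(ratio)
    data.frame(unit_id = id,
               r_absdiff = ra$r, r2_absdiff = ra$r2, p_absdiff = ra$p.value,
               r_ratio = rr$r, r2_ratio = rr$r2, p_ratio = rr$p.value,
               flagged = isTRUE(ra$flagged) || isTRUE(rr$flagged))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
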