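# Independent oracles used to validate the fast implementations.

# blanking by brute force: O(n * m) scan over all (spike, EOD) pairs
bruteBlank <- function(spikeTimes, eodTimes, lo = -2.5, hi = 2.5) {
  keep <- vapply(spikeTimes, function(s) {
    if (!length(eodTimes)) return(TRUE)
    d <- s - eodTimes
    !any(d >= lo & d <= hi)
  }, logical(1))
  spikeTimes[keep]
}

# greedy minimum-variance (Ward) agglomeration by exhaustive pair search;
# returns the partition (list of index sets) after each merge
wardGreedyPartitions <- function(X) {
  groups <- as.list(seq_len(nrow(X)))
  wss <- function(idx) {
    Xi <- X[idx, , drop = FALSE]
    sum(sweep(Xi, 2L, colMeans(Xi))^2)
  }
  out <- list()
  while (length(groups) > 1L) {
    best <- NULL
    bestInc <- Inf
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        inc <- wss(c(groups[[i]], groups[[j]])) -
          wss(groups[[i]]) - wss(groups[[j]])
        if (inc < bestInc) {
          bestInc <- inc
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(groups[[best[1L]]], groups[[best[2L]]]))
    groups <- c(groups[-best], list(merged))
    out[[length(out) + 1L]] <- groups
  }
  out
}

# canonical form of a partition for label-free comparison
canonicalPartition <- function(groups) {
  gs <- lapply(groups, sort)
  gs[order(vapply(gs, `[`, numeric(1), 1L))]
}

cutreePartition <- function(tree, k) {
  lab <- cutree(tree, k)
  canonicalPartition(unname(split(seq_along(lab), lab)))
}

# exact one-sided sign-rank p-value by enumerating all 2^n sign patterns
signrankEnumP <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vAll <- apply(signs, 1L, function(s) sum(r[unlist(s)]))
  if (alternative == "greater") mean(vAll >= vObs) else mean(vAll <= vObs)
}

# direct Davies-Bouldin (centroid form) for a labelled 1-D/2-D dataset
dbDirect <- function(X, labels) {
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
                   numeric(ncol(X))))
  S <- vapply(seq_along(ks), function(i) {
    Xi <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((Xi - rep(cent[i, ], each = nrow(Xi)))^2)))
  }, numeric(1))
  M <- as.matrix(dist(cent))
  mean(vapply(seq_along(ks), function(i)
    max(((S[i] + S[-i]) / M[i, -i])), numeric(1)))
}

# convenience: a small simulated unit with blanked spikes
simUnit <- function(archetype, nEods = 500, seed = NULL) {
  eods <- generateEODTrain(nEods = nEods, seed = seed)
  spikes <- generateUnitSpikes(eods, archetype)
  list(eods = eods, spikes = applyBlanking(spikes, eods))
}
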