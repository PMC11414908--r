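#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, compares the i-th smallest to
#' `alpha / (m - i + 1)` and rejects until the first failure; adjusted
#' p-values are the monotone maxima of `(m - i + 1) * p_(i)`, capped at 1
#' (identical to `p.adjust(method = "holm")`, which is used internally for
#' the adjusted values).
#'
#' @param p numeric vector of p-values.
#' @param alpha significance level for the decisions.
#' @return A list with `adjusted` (adjusted p-values, input order) and
#'   `reject` (logical decisions at `alpha`).
#' @examples
#' holmBonferroni(c(0.01, 0.04), alpha = 0.05)$reject
#' @export
holmBonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be finite in [0, 1]")
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {                       # explicit step-down walk
    if (p[ord[i]] < alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  list(adjusted = p.adjust(p, method = "holm"), reject = reject)
}

#' One-sided Wilcoxon sign-rank test for paired samples
#'
#' Zero differences are dropped before ranking (the standard Wilcoxon
#' convention).  The exact null distribution is used for n <= 25 when the
#' non-zero differences are free of ties; otherwise the normal approximation
#' with continuity correction applies.
#'
#' @param x,y paired samples (or `y = NULL` to test `x` against `mu`).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param mu null location of the differences.
#' @return A list: `statistic` (V), `p.value`, `n` (non-zero pairs),
#'   `alternative`, and `allZero` (`TRUE` when every difference was zero, in
#'   which case p = 1).
#' @examples
#' signrankOneSided(2:6, rep(0, 5))$p.value   # 1/32
#' @export
signrankOneSided <- function(x, y = NULL, alternative = "greater", mu = 0) {
  d <- if (is.null(y)) x - mu else x - y - mu
  d <- d[is.finite(d)]
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p.value = 1, n = 0L,
                alternative = alternative, allZero = TRUE))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(d, alternative = alternative, mu = 0, exact = exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = length(d), alternative = alternative, allZero = FALSE)
}

#' Pearson correlation with coefficient of determination
#'
#' @param x,y numeric vectors (n >= 3).
#' @return A list: `r`, `r2`, `p.value` (two-sided, t reference), `n`, and
#'   `flagged` (`TRUE` when a zero-variance input makes the correlation
#'   undefined; estimates are then `NA`).
#' @examples
#' pearsonWithR2(1:5, c(2, 4, 5, 4, 9))
#' @export
pearsonWithR2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p.value = NA_real_,
                n = length(x), flagged = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p.value = ct$p.value, n = length(x), flagged = FALSE)
}

#' Friedman test with replicated observations
#'
#' Nonparametric two-way analysis for `b` blocks (units), `t` treatments and
#' `r` replicated observations per cell.  Within every block all
#' `t * r` observations are ranked together (average ranks for ties) and the
#' treatment rank sums are accumulated across blocks.  The test statistic is
#' the quadratic form of the centered rank sums against their exact
#' permutation covariance (sampling without replacement within blocks),
#' referred to a chi-squared distribution with `t - 1` degrees of freedom;
#' with one replicate per cell and no ties this reduces exactly to the
#' classical Friedman statistic.  A within-block permutation p-value is
#' available for small designs.
#'
#' @param x numeric array `blocks x treatments x replicates` (for `r = 1` a
#'   `blocks x treatments` matrix is accepted).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param nPerm number of within-block permutations.
#' @return A list: `statistic` (chi-squared), `df`, `p.value`, `rankSums`
#'   (per treatment), and `degenerate` (`TRUE` when all observations are
#'   tied; p = 1).
#' @examples
#' x <- array(rnorm(8 * 2 * 25), c(8, 2, 25))
#' friedmanReplicated(x)$p.value
#' @export
friedmanReplicated <- function(x, method = c("chisq", "permutation"),
                               nPerm = 2000) {
  method <- match.arg(method)
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (length(dim(x)) != 3L) stop("x must be a blocks x treatments x replicates array")
  if (anyNA(x)) stop("missing cells are not supported (no imputation)")
  b <- dim(x)[1L]; tt <- dim(x)[2L]; r <- dim(x)[3L]
  if (b < 2L || tt < 2L) stop("need at least 2 blocks and 2 treatments")
  N <- tt * r

  stat <- function(xx) {
    R <- matrix(0, b, tt)
    s2 <- numeric(b)
    for (i in seq_len(b)) {
      v <- as.vector(xx[i, , ])                 # treatment-major order
      rk <- rank(v)
      R[i, ] <- rowSums(matrix(rk, tt, r))
      s2[i] <- mean((rk - (N + 1) / 2)^2)
    }
    U <- colSums(R) - b * r * (N + 1) / 2
    a <- r * N * sum(s2) / (N - 1)
    list(U = U, a = a, R = colSums(R))
  }
  s <- stat(x)
  if (s$a <= 0)
    return(list(statistic = 0, df = tt - 1L, p.value = 1, rankSums = s$R,
                degenerate = TRUE))
  chisq <- sum(s$U^2) / s$a
  if (method == "chisq") {
    p <- pchisq(chisq, df = tt - 1L, lower.tail = FALSE)
  } else {
    xs <- x
    cnt <- 0L
    for (k in seq_len(nPerm)) {
      for (i in seq_len(b)) {
        v <- as.vector(x[i, , ])
        xs[i, , ] <- array(v[sample.int(N)], c(tt, r))
      }
      sk <- stat(xs)
      if (sum(sk$U^2) / sk$a >= chisq - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1L) / (nPerm + 1L)
  }
  list(statistic = chisq, df = tt - 1L, p.value = p, rankSums = s$R,
       degenerate = FALSE)
}
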