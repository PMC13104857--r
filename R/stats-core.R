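#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic is the supremum over the pooled support of the absolute
#' difference between the two empirical cumulative distribution functions;
#' ties are handled directly by the ECDF definition (no jitter). The
#' p-value uses the asymptotic two-sample Kolmogorov null distribution,
#' which at screen-scale population sizes is indistinguishable from the
#' exact form.
#'
#' @param x,y numeric vectors, non-empty and finite.
#' @return a list with elements `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  n <- length(x); m <- length(y)
  z <- sort(unique(c(x, y)))
  fx <- ecdf_at(x, z)
  fy <- ecdf_at(y, z)
  d <- max(abs(fx - fy))
  ne <- n * m / (n + m)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  p <- ks_q(lambda)
  list(statistic = d, p_value = p)
}

# ECDF of sample at evaluation points (right-continuous, ties natural)
ecdf_at <- function(sample, at) {
  findInterval(at, sort(sample)) / length(sample)
}

# Kolmogorov tail Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
ks_q <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

check_sample <- function(v, name) {
  if (length(v) == 0) stop("`", name, "` is empty")
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("`", name, "` must be numeric and finite")
  invisible(v)
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Standard step-up false-discovery-rate control: adjusted p-values in the
#' input order, with rejection where the adjusted p-value is strictly
#' below `alpha`.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance threshold in `(0, 1)`.
#' @return a list with `adjusted` (numeric) and `rejected` (logical), both
#'   in input order.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = adj < alpha)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with tie correction (normal approximation). The statistic
#' is U for `x` versus `y`: the number of pairs with `x > y` plus half the
#' ties, so complete separation with `x` below `y` gives `U = 0`.
#'
#' @param x,y numeric vectors, non-empty.
#' @return a list with `statistic` (U) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the
#' t approximation. Constant input is an error -- the correlation is
#' undefined there, and reporting 0 silently would hide it.
#'
#' @param x,y numeric vectors of equal length at least 3.
#' @return a list with `statistic` (rho) and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal lengths")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant input: Spearman correlation undefined")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(statistic = rho, p_value = p)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among `m` judges each ranking the same `n` items:
#' `W = 12 S / (m^2 (n^3 - n))` where `S` is the sum of squared deviations
#' of per-item rank sums from their mean. When rows contain midranks the
#' tie correction subtracts `m * sum_i T_i` from the denominator, with
#' `T_i = sum (t^3 - t)` over tie groups of judge `i`. W is 1 for
#' identical rankings and 0 when rank sums are constant.
#'
#' @param ranks numeric matrix, one row per judge, one column per item;
#'   each row a (midrank-resolved) ranking of the items.
#' @param tie_correction apply the midrank tie correction (default TRUE).
#' @return W, a number in `[0, 1]`.
#' @export
kendalls_w <- function(ranks, tie_correction = TRUE) {
  ranks <- as.matrix(ranks)
  m <- nrow(ranks); n <- ncol(ranks)
  if (m < 2) stop("need at least 2 judges (rows)")
  if (n < 2) stop("need at least 2 items (columns)")
  if (anyNA(ranks)) stop("rank matrix must be complete")
  # normalise each row to midranks of itself so arbitrary scores also work
  ranks <- t(apply(ranks, 1, rank))
  colsums <- colSums(ranks)
  s <- sum((colsums - mean(colsums))^2)
  denom <- m^2 * (n^3 - n)
  if (tie_correction) {
    tt <- sum(apply(ranks, 1, function(r) {
      tab <- table(r)
      sum(tab^3 - tab)
    }))
    denom <- denom - m * tt
  }
  if (denom <= 0) {
    # every judge ties all items: no information, perfect (vacuous) agreement
    return(1)
  }
  w <- 12 * s / denom
  min(1, max(0, w))
}

#' Empirical p-value from a permutation null
#'
#' Proportion of null samples at least as extreme as the observed value in
#' the given direction; ties count as extreme. The `(1 + k) / (1 + N)`
#' small-sample correction is available but off by default, matching the
#' plain-proportion definition used throughout the package's permutation
#' analyses.
#'
#' @param observed observed statistic.
#' @param null_samples numeric vector of null statistics, non-empty.
#' @param direction `"ge"` (null >= observed is extreme) or `"le"`.
#' @param add_one apply the `+1` correction.
#' @return a proportion in `[0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_samples,
                             direction = c("ge", "le"), add_one = FALSE) {
  direction <- match.arg(direction)
  if (length(null_samples) == 0) stop("`null_samples` is empty")
  k <- switch(direction,
              ge = sum(null_samples >= observed),
              le = sum(null_samples <= observed))
  if (add_one) (1 + k) / (1 + length(null_samples))
  else k / length(null_samples)
}
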