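# Independent brute-force oracles for the statistical kernels. These are
# deliberately naive implementations that share no code with the package.

# max ECDF gap by direct evaluation at every pooled point
oracle_ks_stat <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# BH step-up by literal threshold enumeration
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# U by exhaustive pair counting: pairs with x > y plus half the ties
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Pearson on midranks, from first principles
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Kendall's W by direct evaluation of the tie-corrected formula
oracle_w <- function(ranks) {
  ranks <- t(apply(ranks, 1, rank))
  m <- nrow(ranks); n <- ncol(ranks)
  rs <- colSums(ranks)
  s <- sum((rs - mean(rs))^2)
  tt <- 0
  for (i in seq_len(m)) {
    for (t in table(ranks[i, ])) tt <- tt + t^3 - t
  }
  12 * s / (m^2 * (n^3 - n) - m * tt)
}

# exact EMD for uniform point masses via assignment on the lcm expansion
# (Hungarian algorithm from clue); independent of the package's simplex
oracle_emd <- function(x, y) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  n <- nrow(x); m <- nrow(y)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  L <- n * m / gcd(n, m)
  cost <- as.matrix(stats::dist(rbind(x, y)))[seq_len(n), n + seq_len(m),
                                              drop = FALSE]
  big <- cost[rep(seq_len(n), each = L / n),
              rep(seq_len(m), each = L / m), drop = FALSE]
  sol <- clue::solve_LSAP(big)
  sum(big[cbind(seq_len(L), sol)]) / L
}
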