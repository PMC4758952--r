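# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (probability-mass method).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  logp <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(-Inf)
    lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1)
  }
  amax <- min(r1, c1)
  lps <- vapply(0:amax, logp, numeric(1))
  obs <- logp(tab[1, 1])
  sum(exp(lps[lps <= obs + 1e-7]))
}

# Brute-force MAP segmentation by enumerating all 2^(n-1) partitions with
# the same block score the package uses (Poisson-Gamma marginal likelihood
# with the partition-constant term dropped, geometric block-length prior).
oracle_segment_bruteforce <- function(counts, alpha = 1, beta = 1,
                                      p = 0.01) {
  n <- length(counts)
  block_score <- function(i, j) {  # bins i..j inclusive
    S <- sum(counts[i:j]); L <- j - i + 1
    alpha * log(beta) - lgamma(alpha) + lgamma(alpha + S) -
      (alpha + S) * log(beta + L) + (L - 1) * log1p(-p) + log(p)
  }
  best <- -Inf; best_bounds <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(cuts, n)  # block right edges
    starts <- c(1, head(bounds, -1) + 1)
    sc <- sum(mapply(block_score, starts, bounds))
    if (sc > best) { best <- sc; best_bounds <- bounds }
  }
  list(end_bin = best_bounds, score = best)
}

# Partial correlation as the correlation of OLS residuals.
oracle_partial_resid <- function(m, x, y, given, rank_first = TRUE) {
  if (rank_first) m <- apply(m, 2, rank)
  if (length(given) == 0) return(stats::cor(m[, x], m[, y]))
  Z <- m[, given, drop = FALSE]
  rx <- stats::resid(stats::lm(m[, x] ~ Z))
  ry <- stats::resid(stats::lm(m[, y] ~ Z))
  stats::cor(rx, ry)
}

# Nearest-rank percentile (re-stated independently of the package).
oracle_nearest_rank <- function(v, p) sort(v)[max(1, ceiling(p * length(v)))]
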