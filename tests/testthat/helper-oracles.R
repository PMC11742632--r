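# Independent brute-force oracles used to check the statistical machinery.
# These deliberately avoid the code paths they verify.

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to group A (requires untied data).
mwExactOracle <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a); nB <- length(b)
  uOf <- function(av, bv) sum(outer(av, bv, ">"))
  uObs <- uOf(a, b)
  splits <- utils::combn(length(pooled), nA)
  uAll <- apply(splits, 2L, function(idx) uOf(pooled[idx], pooled[-idx]))
  if (uObs == nA * nB / 2) return(1)
  if (uObs < nA * nB / 2) {
    min(1, 2 * mean(uAll <= uObs))
  } else {
    min(1, 2 * mean(uAll >= uObs))
  }
}

# Brute-force Benjamini-Hochberg: explicit step-up rejection rule and
# backward cumulative-min adjusted p-values.
bhOracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- seq_len(m) * q / m
  below <- which(ps <= crit)
  k <- if (length(below)) max(below) else 0L
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  adjSorted <- rev(cummin(rev(m * ps / seq_len(m))))
  adjSorted <- pmin(adjSorted, 1)
  adj <- numeric(m)
  adj[o] <- adjSorted
  list(p_adjusted = adj, reject = reject)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration (sum of all table probabilities not exceeding the observed,
# with the customary 1e-7 relative tolerance).
fisherOracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Closed-form OLS slope for one response vector.
olsSlopeOracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}
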