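# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each statistic from first principles and
# never call the code path they verify.

# two-group log-rank chi-square from an explicitly enumerated risk-set
# table (hypergeometric variance for tied event times)
logrank_oracle <- function(time, event, in_group1) {
  event_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# two-sided Fisher exact p for a 2x2 table by exhaustive enumeration of the
# hypergeometric tail (point-probability method)
fisher_oracle <- function(n11, n10, n01, n00) {
  m <- n11 + n10
  n <- n01 + n00
  k <- n11 + n01
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(n11, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho by the classical rank-difference formula (untied values)
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# node degree by direct adjacency recount within the candidate set
degree_oracle <- function(edges, candidates) {
  sub <- edges[edges$node_a %in% candidates & edges$node_b %in% candidates, ]
  vapply(candidates, function(v) {
    sum(sub$node_a == v) + sum(sub$node_b == v)
  }, numeric(1))
}

# 99% binomial band around a rate
binomial_band <- function(p, n, level = 0.99) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}
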