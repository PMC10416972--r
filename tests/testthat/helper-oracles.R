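# Independent oracles. These deliberately avoid the package's code paths:
# the t oracle is the textbook pooled-variance formula with the p-value from
# the regularized incomplete beta function; the hypergeometric oracle is
# brute-force enumeration of all query draws.

# Textbook two-sample equal-variance Student's t: statistic, df, and
# two-sided p via the incomplete-beta representation
# P(|T| > t) = I_{df/(df + t^2)}(df/2, 1/2).
oracle_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- stats::pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, df = df, p = p)
}

# Brute-force upper-tail hypergeometric: enumerate every size-n draw from a
# universe of N items whose first K are "in the set"; return P(overlap >= k).
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}
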