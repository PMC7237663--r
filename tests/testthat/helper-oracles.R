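# Independent brute-force oracles used to freeze expected values.

# Two-sided rank-sum p by full enumeration of all group assignments.
enumWilcoxonTwoSided <- function(a, b) {
  x <- c(a, b)
  n <- length(x)
  na <- length(a)
  r <- rank(x)
  w_obs <- sum(r[seq_len(na)])
  combs <- utils::combn(n, na)
  w_all <- colSums(matrix(r[combs], nrow = na))
  mu <- na * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force BH step-up.
bruteBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by enumerating every draw of n from N.
bruteHyperUpper <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  combs <- utils::combn(N, n)
  ov <- colSums(matrix(combs <= K, nrow = n))
  mean(ov >= k)
}

# Coarse grid-search ML fit of a 2-component 1-D Gaussian mixture.
gridGmmLoglik <- function(x) {
  mus <- seq(min(x), max(x), length.out = 15)
  sds <- seq(0.3, 1.5, length.out = 5) * sd(x)
  ws <- c(0.25, 0.5, 0.75)
  best <- -Inf
  for (m1 in mus) for (m2 in mus[mus >= m1]) for (s1 in sds)
    for (s2 in sds) for (w in ws) {
      ll <- sum(log(w * dnorm(x, m1, s1) + (1 - w) * dnorm(x, m2, s2)))
      if (ll > best) best <- ll
    }
  best
}
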