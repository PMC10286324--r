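# Independent brute-force oracles, kept free of the package's code paths.

# Exact two-sided rank-sum p by enumerating all assignments of the pooled
# values to the first group; extremity = |rank sum - permutation mean|.
oracleRankSumP <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  n <- length(pooled)
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combs <- combn(n, nx)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}

oracleRankSumPGreater <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w <- sum(r[seq_len(nx)])
  combs <- combn(length(pooled), nx)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(sums >= w - 1e-9)
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial summation.
oracleHyperP <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Textbook Benjamini-Hochberg step-up.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hand product-limit estimator (right censoring).
oracleKM <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    nAtRisk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / nAtRisk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Two-group log-rank chi-square from the hypergeometric moments at each
# distinct event time.
oracleLogRank2 <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L # 0/1
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Monte-Carlo permutation p for the log-rank statistic.
permutationLogRankP <- function(time, event, group, B = 10000, seed = 1) {
  set.seed(seed)
  obs <- oracleLogRank2(time, event, group)
  perm <- replicate(B, oracleLogRank2(time, event, sample(group)))
  mean(perm >= obs - 1e-12)
}
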