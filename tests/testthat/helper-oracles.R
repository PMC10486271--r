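# Independent brute-force oracles used across test files.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all C(n1+n2, n1)
# group assignments (no ties assumed).
wilcox_enum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(r), n1)
  ws <- apply(idx, 2, function(i) sum(seq_along(r)[i]))
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Benjamini-Hochberg step-up by direct definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-group log-rank chi-square by the hand-expanded (sum(O-E))^2 / sum(V)
# formula over distinct event times.
logrank_brute <- function(time, event, group) {
  g <- as.character(group)
  lv <- sort(unique(g))
  stopifnot(length(lv) == 2)
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == lv[1])
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Upper-tail hypergeometric P(X >= k) by direct pmf summation.
hyper_tail_brute <- function(k, set_size, universe_size, query_size) {
  i <- k:min(set_size, query_size)
  sum(choose(set_size, i) * choose(universe_size - set_size, query_size - i)) /
    choose(universe_size, query_size)
}

# Kaplan-Meier product-limit by direct hand computation.
km_brute <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
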