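# Independent brute-force oracles, deliberately naive (explicit loops and
# enumeration) and kept free of any package internals. They operate on
# plain value vectors assumed to sit on consecutive days.

oracle_pct_var <- function(v) {
  n <- length(v)
  if (n < 2L) return(NA_real_)
  cnt <- 0L
  for (t in 1:(n - 1L)) if (v[t + 1L] != v[t]) cnt <- cnt + 1L
  100 * cnt / (n - 1L)
}

oracle_ivi <- function(v, S = 1, plus_one = FALSE) {
  pv <- oracle_pct_var(v)
  if (is.na(pv)) return(NA_real_)
  r <- (max(v) - min(v)) / S
  if (plus_one) r <- r + 1
  if (r == 0) 0 else pv / r
}

oracle_pct_zero <- function(v) {
  if (!length(v)) return(NA_real_)
  100 * sum(v == 0) / length(v)
}

oracle_cv <- function(v) {
  n <- length(v)
  if (n < 2L) return(NA_real_)
  m <- sum(v) / n
  if (m == 0) return(NA_real_)
  s2 <- sum((v - m)^2) / (n - 1L)
  100 * sqrt(s2) / m
}

oracle_trend <- function(v) {
  n <- length(v)
  if (n < 3L) return(NA_real_)
  s <- integer(n - 1L)
  for (t in 1:(n - 1L)) {
    s[t] <- if (v[t + 1L] > v[t]) 1L else if (v[t + 1L] < v[t]) -1L else 0L
  }
  ch <- 0L
  for (t in 2:length(s)) if (s[t] != s[t - 1L]) ch <- ch + 1L
  100 * ch / (length(s) - 1L)
}

# U statistic of x vs y (pairs with x > y, half credit for ties)
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Exact two-sided Mann-Whitney p by full enumeration of all assignments of
# the pooled values to the two groups (no-ties case).
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2L, function(ii) oracle_u(pooled[ii], pooled[-ii]))
  u_obs <- oracle_u(x, y)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Spearman rho from scratch: mid-ranks, then the Pearson formula by hand.
oracle_rank <- function(v) {
  sapply(v, function(z) sum(v < z) + (sum(v == z) + 1) / 2)
}

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
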