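# Independent brute-force oracles used to check exact small-sample p-values.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (average ranks under ties).
mw_exact_p_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  e_w <- n * (n + m + 1) / 2
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns.
signed_rank_exact_p_enum <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  e_v <- n * (n + 1) / 4
  mean(abs(v_all - e_v) >= abs(v_obs - e_v) - 1e-12)
}

# Hand moving average with centred window and edge shrink.
moving_average_oracle <- function(v, k) {
  n <- length(v)
  h1 <- floor((k - 1) / 2); h2 <- ceiling((k - 1) / 2)
  sapply(seq_len(n), function(i) mean(v[max(1, i - h1):min(n, i + h2)],
                                      na.rm = TRUE))
}
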