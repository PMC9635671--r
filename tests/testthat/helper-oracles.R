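# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementations they check.

# per-point sorted-median rolling filter with symmetric shrinking edges
oracle_rolling_median <- function(x, window) {
  n <- length(x)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    sort(x[(i - h):(i + h)])[h + 1]
  }, numeric(1))
}

# naive truncated-Gaussian convolution, renormalized at the edges
oracle_gaussian <- function(x, sigma) {
  n <- length(x)
  L <- ceiling(4 * sigma)
  w <- exp(-((-L:L)^2) / (2 * sigma^2))
  vapply(seq_len(n), function(i) {
    idx <- (i - L):(i + L)
    ok <- idx >= 1 & idx <= n
    sum(w[ok] * x[idx[ok]]) / sum(w[ok])
  }, numeric(1))
}

# exhaustive all-window OLS slope scan of log2(cells) on time; per-window
# slopes via the textbook sum formula (use_lm = TRUE cross-checks with lm)
oracle_max_slope <- function(time_h, cells, window = 5, use_lm = FALSE) {
  y <- log2(cells)
  n <- length(y)
  best_slope <- -Inf
  best_start <- NA_integer_
  for (s in 1:(n - window + 1)) {
    idx <- s:(s + window - 1)
    if (use_lm) {
      sl <- unname(coef(lm(y[idx] ~ time_h[idx]))[2])
    } else {
      tw <- time_h[idx] - mean(time_h[idx])
      sl <- sum(tw * (y[idx] - mean(y[idx]))) / sum(tw^2)
    }
    if (is.infinite(best_slope) ||
        sl > best_slope + 1e-9 * max(abs(best_slope), 1)) {
      best_slope <- sl
      best_start <- s
    }
  }
  list(slope = best_slope, start = best_start)
}

# hand-applied Benjamini-Hochberg step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher p for an overlap table by exhaustive hypergeometric
# summation over all possible overlaps
oracle_fisher_two_sided <- function(overlap, n_a, n_b, n_u) {
  ks <- max(0, n_a + n_b - n_u):min(n_a, n_b)
  probs <- vapply(ks, function(k) {
    choose(n_a, k) * choose(n_u - n_a, n_b - k) / choose(n_u, n_b)
  }, numeric(1))
  p_obs <- probs[ks == overlap]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# a clean lag-exponential-plateau curve (noise-free forward model)
make_clean_curve <- function(D = 2, lag = 2, n0 = 5e4, cap = 3e6,
                             dt = 1 / 3, duration = 72) {
  t <- seq(0, duration, by = dt)
  cells <- pmin(n0 * 2^(pmax(0, t - lag) / D), cap)
  list(time_h = t, cells = cells)
}
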