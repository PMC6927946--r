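# Independent oracles used across the suite.

# All label sequences of length `len` satisfying exact per-bin balance and
# the run cap, by exhaustive enumeration (small instances only).
enumerate_admissible <- function(block_length, bin_size, per_bin_splus, max_run) {
  stopifnot(block_length <= 12)
  grid <- expand.grid(rep(list(c("S+", "S-")), block_length),
                      stringsAsFactors = FALSE)
  keep <- apply(grid, 1, function(lab) {
    n_bins <- block_length / bin_size
    for (b in seq_len(n_bins)) {
      bin <- lab[((b - 1) * bin_size + 1):(b * bin_size)]
      if (sum(bin == "S+") != per_bin_splus) return(FALSE)
    }
    max(rle(lab)$lengths) <= max_run
  })
  unname(apply(grid[keep, , drop = FALSE], 1, paste, collapse = ""))
}

# Inverse standard-normal CDF by bisection on pnorm (independent of qnorm).
qnorm_bisect <- function(p, lo = -10, hi = 10, tol = 1e-12) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

dprime_oracle <- function(hits, misses, fa, cr) {
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  h <- clamp(hits / (hits + misses), hits + misses)
  f <- clamp(fa / (fa + cr), fa + cr)
  qnorm_bisect(h) - qnorm_bisect(f)
}

# Pearson r from the raw covariance/variance sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  sxy / sqrt(sxx * syy)
}

# A compliant, always-correct agent with constant round-the-clock activity.
flawless_agent <- function(rate = 50) {
  agent_params(h0 = 1, h_inf = 1, f0 = 0, f_inf = 0,
               p_rfid_fail = 0, p_presample_fail = 0,
               activity_rate = rep(rate, 24))
}

# Busy interval [start, end] of each record for port-exclusion checks.
record_intervals <- function(rec) {
  busy <- ifelse(rec$outcome == "ABORTED" & rec$odor_id == "none", 0.5,
                 0.5 + rec$odor_on_ms / 1000 + rec$iti_s)
  data.frame(start = rec$time_s, end = rec$time_s + busy)
}
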