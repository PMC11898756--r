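# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: least squares via explicit normal equations,
# digestion via brute force over all substring boundaries.

# closed-form simple linear regression of y on x (normal equations)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  det <- n * sxx - sx * sx
  slope <- (n * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# brute-force trypsin/P enumerator: every substring whose start follows a
# K/R (or is the N-terminus) and whose end is a K/R (or the C-terminus),
# with the number of internal K/R sites as missed cleavages
digest_oracle <- function(seq, max_missed = 2L, min_len = 7L) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  is_site <- res %in% c("K", "R")
  peps <- character(0)
  for (s in 1:n) {
    if (s > 1 && !is_site[s - 1]) next
    for (e in s:n) {
      if (e < n && !is_site[e]) next
      internal <- if (e > s) sum(is_site[s:(e - 1)]) else 0L
      if (internal > max_missed) next
      if (e - s + 1L < min_len) next
      peps <- c(peps, substr(seq, s, e))
    }
  }
  sort(peps)
}

# hand-evaluated Welch t statistic and Satterthwaite df
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# noiseless heavy/light ratio under the dilution/production kinetic scheme
hl_closed_form <- function(t_min, mu_per_h, a1_over_a0 = 1, k_deg = 0) {
  k <- (mu_per_h + k_deg) / 60
  a1_over_a0 * (exp(k * t_min) - 1)
}

sim_dilution_scenario <- function(mu, times, n = 600, noise_cv = 0.2,
                                  seed = 42L) {
  cfg <- simulation_config(n_proteins = n, mu_post = mu,
                           sampling_times = times, noise_cv = noise_cv,
                           seed = seed)
  simulate_labeling_experiment(cfg, dilution_only_truths(n, seed = seed + 1L))
}
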