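# Shared fixtures and independent oracles used across the suite.

# Build a dF/F0 tibble directly from a percent vector, bypassing the
# baseline step, for detector tests with hand-constructed waveforms.
make_dff <- function(dff_pct, larva_id = "L1", group = "control", fs = 1) {
  n <- length(dff_pct)
  tibble::tibble(
    larva_id = larva_id, group = group, treatment = "none",
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1) / fs,
    f = 100 * (1 + dff_pct / 100), f0 = 100,
    sampling_rate_hz = fs, dff_pct = as.numeric(dff_pct)
  )
}

# A noiseless, driftless simulation config for exact-recovery tests.
quiet_cfg <- function(duration_s = 600, ...) {
  sim_config(duration_s = duration_s, noise_sd_pct = 0,
             drift = list(amplitude_fraction = 0, period_s = 1800), ...)
}

# Brute-force moving-window percentile: collect the window, sort,
# interpolate (type 7). The independent oracle for the baseline.
baseline_oracle <- function(f, window_s, percentile, fs,
                            align = c("centered", "trailing")) {
  align <- match.arg(align)
  n <- length(f)
  vapply(seq_len(n), function(k) {
    if (align == "centered") {
      half <- round(window_s * fs / 2)
      idx <- max(1, k - half):min(n, k + half)
    } else {
      before <- max(round(window_s * fs) - 1, 1)
      idx <- max(1, k - before):k
    }
    unname(quantile(sort(f[idx]), percentile / 100, type = 7))
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  combs <- utils::combn(n1 + n2, n1)
  # U statistic of the second sample under each assignment of labels
  u_obs <- sum(rank(pooled)[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  u_all <- apply(combs, 2, function(idx) {
    sum(ranks[-idx]) - n2 * (n2 + 1) / 2
  })
  center <- n1 * n2 / 2
  p <- if (u_obs > center) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# NB counts with mean mu and gamma-Poisson dispersion phi (var = mu + phi*mu^2).
rnb <- function(n, mu, phi) rnbinom(n, size = 1 / phi, mu = mu)
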