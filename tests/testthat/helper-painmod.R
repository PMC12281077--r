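# Shared fixtures and independent oracles (kept deliberately naive: plain
# loops, no reuse of package internals).

# A constant-rating trace on the paradigm's grid, built sample by sample.
constant_trace <- function(value, timing, subject_id = "const", series = 1L,
                           isi_value = 0) {
  dt <- timing$sample_interval
  times <- c(); vals <- c()
  for (k in seq_len(timing$n_blocks)) {
    start <- (k - 1) * (timing$stimulus_duration + timing$isi_duration)
    n_stim <- floor(timing$stimulus_duration / dt + 1e-9)
    n_isi <- floor(timing$isi_duration / dt + 1e-9)
    times <- c(times, start + dt * (0:(n_stim - 1)),
               start + timing$stimulus_duration + dt * (0:(n_isi - 1)))
    vals <- c(vals, rep(value, n_stim), rep(isi_value, n_isi))
  }
  data.frame(subject_id = subject_id, series = as.integer(series),
             time_s = times, vas = vals)
}

# A trace whose in-block level is given per block (zero jitter).
levelled_trace <- function(levels, timing, subject_id = "lev", series = 1L) {
  dt <- timing$sample_interval
  times <- c(); vals <- c()
  for (k in seq_len(timing$n_blocks)) {
    start <- (k - 1) * (timing$stimulus_duration + timing$isi_duration)
    n_stim <- floor(timing$stimulus_duration / dt + 1e-9)
    n_isi <- floor(timing$isi_duration / dt + 1e-9)
    times <- c(times, start + dt * (0:(n_stim - 1)),
               start + timing$stimulus_duration + dt * (0:(n_isi - 1)))
    vals <- c(vals, rep(levels[k], n_stim), rep(0, n_isi))
  }
  data.frame(subject_id = subject_id, series = as.integer(series),
             time_s = times, vas = vals)
}

# Brute-force window mean: flat loop over every sample, [from, to).
oracle_window_mean <- function(trace, from, to) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(trace))) {
    t <- trace$time_s[i]
    if (t >= from - 1e-9 && t < to - 1e-9) { tot <- tot + trace$vas[i]; n <- n + 1 }
  }
  tot / n
}

oracle_block_means <- function(trace, timing) {
  sapply(seq_len(timing$n_blocks), function(k) {
    start <- (k - 1) * (timing$stimulus_duration + timing$isi_duration)
    oracle_window_mean(trace, start, start + timing$stimulus_duration)
  })
}

# Textbook pooled two-proportion z, written independently of the package.
oracle_two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2; p <- (k1 + k2) / (n1 + n2)
  (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

# Quick block-mean pair for a null or shifted subject (used by classifier
# calibration/power tests); draws directly from the generative law of the
# block means rather than through traces.
draw_block_pair <- function(baseline = 45, delta = 0, noise_sd = 5) {
  list(control = baseline + rnorm(8, 0, noise_sd),
       test = baseline + delta + rnorm(8, 0, noise_sd))
}
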