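#' Stimulus-block schedule for one pain-modulation paradigm
#'
#' Returns the fixed timing of a recording series: eight noxious heat blocks
#' separated by non-painful interstimulus intervals (ISI), with continuous
#' VAS sampling every 0.5 s.
#'
#' Placebo analgesia and conditioned pain modulation (CPM) use 15 s stimulus
#' blocks (including a 2.5 s thermode ramp up and down at 4 degC/s) and a
#' 15 s ISI. Offset analgesia uses a fast thermode with an effectively
#' instantaneous ramp, 14.4 s blocks and a 14.4 s ISI; within each offset
#' block of the second (offset) series the temperature profile is T1 = 4 s at
#' the moderate temperature, T2 = 4 s raised by 1 degC, T3 = 6.4 s back at
#' the moderate temperature.
#'
#' @param paradigm one of `"placebo"`, `"cpm"`, `"offset"`.
#' @return an object of class `paradigm_timing`: a list with fields
#'   `paradigm`, `n_blocks` (8), `stimulus_duration`, `isi_duration`,
#'   `sample_interval` (0.5 s), `ramp_rate` (degC/s, `Inf` for offset) and,
#'   for offset only, `t1`, `t2`, `t3` (seconds).
#' @examples
#' paradigm_timing("placebo")
#' paradigm_timing("offset")$t3
#' @export
paradigm_timing <- function(paradigm = c("placebo", "cpm", "offset")) {
  if (length(paradigm) != 1L || !is.character(paradigm) ||
      !paradigm %in% c("placebo", "cpm", "offset")) {
    stop_painmod(
      sprintf("unknown paradigm '%s'; must be one of 'placebo', 'cpm', 'offset'",
              paste(paradigm, collapse = ",")),
      "painmod_unknown_paradigm")
  }
  tm <- if (paradigm == "offset") {
    list(paradigm = paradigm, n_blocks = 8L,
         stimulus_duration = 14.4, isi_duration = 14.4,
         sample_interval = 0.5, ramp_rate = Inf,
         t1 = 4.0, t2 = 4.0, t3 = 6.4)
  } else {
    list(paradigm = paradigm, n_blocks = 8L,
         stimulus_duration = 15.0, isi_duration = 15.0,
         sample_interval = 0.5, ramp_rate = 4,
         t1 = NA_real_, t2 = NA_real_, t3 = NA_real_)
  }
  class(tm) <- "paradigm_timing"
  validate_timing(tm)
  tm
}

validate_timing <- function(tm) {
  stopifnot(inherits(tm, "paradigm_timing"))
  if (tm$n_blocks != 8L)
    stop_painmod("timing must have 8 blocks", "painmod_invalid_timing")
  if (tm$paradigm == "offset") {
    if (!isTRUE(all.equal(tm$t1 + tm$t2 + tm$t3, tm$stimulus_duration)))
      stop_painmod("offset T1+T2+T3 must equal the stimulus duration",
                   "painmod_invalid_timing")
    if (any(c(tm$t1, tm$t2, tm$t3) <= 0))
      stop_painmod("offset T1/T2/T3 must be positive", "painmod_invalid_timing")
  }
  invisible(tm)
}

#' @export
print.paradigm_timing <- function(x, ...) {
  cat(sprintf("<paradigm_timing> %s: %d blocks of %.1f s, ISI %.1f s, sampled every %.1f s\n",
              x$paradigm, x$n_blocks, x$stimulus_duration, x$isi_duration,
              x$sample_interval))
  if (x$paradigm == "offset")
    cat(sprintf("  offset windows: T1 %.1f s, T2 %.1f s (+1 degC), T3 %.1f s\n",
                x$t1, x$t2, x$t3))
  invisible(x)
}

# Block onset times (seconds) within a series.
block_starts <- function(tm) {
  (seq_len(tm$n_blocks) - 1) * (tm$stimulus_duration + tm$isi_duration)
}

# Number of samples in a window of `dur` seconds anchored at its own onset.
# Sampling restarts at each segment onset, so a segment holds
# floor(dur / dt) samples at offsets 0, dt, 2 dt, ... (half-open window).
samples_per_window <- function(dur, dt) as.integer(floor(dur / dt + 1e-9))

# Total series duration in seconds.
series_duration <- function(tm) tm$n_blocks * (tm$stimulus_duration + tm$isi_duration)
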