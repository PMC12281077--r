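# Reduction of continuous VAS traces to per-stimulus-block summaries.
#
# All windows are half-open [start, end): a sample at an exact boundary
# belongs to the later window, so consecutive windows never double count.
# With sampling anchored at each block onset, a 15 s block at 0.5 s holds 30
# samples and the offset T1/T2/T3 windows hold exactly 8/8/12 samples.

# Mean of trace samples falling in [from, to) for one subject/series.
window_mean <- function(times, values, from, to, dt, what) {
  sel <- times >= from - 1e-9 & times < to - 1e-9
  n_expected <- samples_per_window(to - from, dt)
  n_got <- sum(sel)
  if (n_got < n_expected) {
    stop_painmod(sprintf("%s: expected %d samples in [%g, %g), found %d (no imputation is performed)",
                         what, n_expected, from, to, n_got),
                 "painmod_missing_samples")
  }
  mean(values[sel])
}

as_trace <- function(trace) {
  if (inherits(trace, "vas_trace")) return(trace)
  req <- c("subject_id", "series", "time_s", "vas")
  if (!is.data.frame(trace) || !all(req %in% names(trace)))
    stop_painmod("trace must have columns subject_id, series, time_s, vas",
                 "painmod_invalid_input")
  trace
}

block_series <- function(trace, means, window_label) {
  out <- list(subject_id = trace$subject_id[1],
              series = trace$series[1],
              block_means = as.numeric(means),
              window_label = window_label)
  class(out) <- "block_series"
  out
}

#' Per-block mean VAS over the full stimulus windows
#'
#' Averages the continuous ratings over each of the eight stimulus blocks
#' (the whole block, ramps included), giving the eight pain-intensity values
#' that the classifier and all variability statistics consume.
#'
#' @param trace a `vas_trace` (or data.frame with columns `subject_id`,
#'   `series`, `time_s`, `vas`) holding one subject's one series.
#' @param timing the matching [paradigm_timing()].
#' @return an object of class `block_series` with fields `subject_id`,
#'   `series`, `block_means` (length 8) and `window_label = "full_block"`.
#' @examples
#' pr <- subject_profile("demo", block_noise_sd = 0, within_block_sd = 0)
#' tm <- paradigm_timing("placebo")
#' block_means(simulate_trace(pr, tm, 1), tm)$block_means
#' @export
block_means <- function(trace, timing) {
  trace <- as_trace(trace)
  stopifnot(inherits(timing, "paradigm_timing"))
  starts <- block_starts(timing)
  if (max(trace$time_s) < starts[timing$n_blocks])
    stop_painmod("trace is shorter than the stimulus schedule",
                 "painmod_missing_samples")
  m <- vapply(seq_along(starts), function(k) {
    window_mean(trace$time_s, trace$vas, starts[k],
                starts[k] + timing$stimulus_duration,
                timing$sample_interval, sprintf("block %d", k))
  }, numeric(1))
  block_series(trace, m, "full_block")
}

#' Per-block mean VAS over the offset T3 window
#'
#' For the offset series (series 2 of the offset paradigm) the analysed
#' rating window is T3: the final 6.4 s of each block, after the temperature
#' has stepped back down by 1 degC.
#'
#' @inheritParams block_means
#' @return a `block_series` with `window_label = "offset_T3"`.
#' @export
offset_t3_means <- function(trace, timing) {
  trace <- as_trace(trace)
  stopifnot(inherits(timing, "paradigm_timing"))
  if (timing$paradigm != "offset")
    stop_painmod("T3 windows exist only for the offset paradigm",
                 "painmod_wrong_paradigm")
  validate_timing(timing)
  starts <- block_starts(timing)
  m <- vapply(seq_along(starts), function(k) {
    window_mean(trace$time_s, trace$vas, starts[k] + timing$t1 + timing$t2,
                starts[k] + timing$stimulus_duration,
                timing$sample_interval, sprintf("T3 of block %d", k))
  }, numeric(1))
  block_series(trace, m, "offset_T3")
}

#' Per-block mean VAS over the last 6.4 s of each control block
#'
#' The offset comparison window in the control series: the last `t3` seconds
#' of each constant-temperature block, time-matched to the T3 window of the
#' offset series.
#'
#' @inheritParams block_means
#' @return a `block_series` with `window_label = "control_last_6.4s"`.
#' @export
control_tail_means <- function(trace, timing) {
  trace <- as_trace(trace)
  stopifnot(inherits(timing, "paradigm_timing"))
  if (timing$paradigm != "offset")
    stop_painmod("control tail windows exist only for the offset paradigm",
                 "painmod_wrong_paradigm")
  validate_timing(timing)
  starts <- block_starts(timing)
  m <- vapply(seq_along(starts), function(k) {
    window_mean(trace$time_s, trace$vas,
                starts[k] + timing$stimulus_duration - timing$t3,
                starts[k] + timing$stimulus_duration,
                timing$sample_interval, sprintf("control tail of block %d", k))
  }, numeric(1))
  block_series(trace, m, "control_last_6.4s")
}

#' Rating variability of one series
#'
#' The sample standard deviation (n - 1 denominator) of the eight block
#' means: the per-series pain-intensity variability measure.
#'
#' @param series a `block_series` (or a plain numeric vector of 8 means).
#' @return a list with `subject_id`, `series` and `sd_of_block_means`.
#' @examples
#' series_variability(c(0, 0, 0, 0, 10, 10, 10, 10))$sd_of_block_means
#' @export
series_variability <- function(series) {
  if (is.numeric(series)) {
    v <- series
    sid <- NA_character_; sidx <- NA_integer_
  } else {
    stopifnot(inherits(series, "block_series"))
    v <- series$block_means
    sid <- series$subject_id; sidx <- series$series
  }
  if (length(v) != 8L)
    stop_painmod("a block-mean series must have exactly 8 values",
                 "painmod_invalid_input")
  check_finite_numeric(v, "block means")
  list(subject_id = sid, series = sidx, sd_of_block_means = stats::sd(v))
}

# The windowed series pair fed to the classifier for one subject.
# Placebo/CPM compare full blocks of both series; offset compares the
# control-tail window of series 1 with the T3 window of series 2.
windowed_pair <- function(trace1, trace2, timing) {
  if (timing$paradigm == "offset") {
    list(control = control_tail_means(trace1, timing),
         test = offset_t3_means(trace2, timing))
  } else {
    list(control = block_means(trace1, timing),
         test = block_means(trace2, timing))
  }
}

#' Block-mean table for a whole cohort
#'
#' Applies the paradigm's analysis windows to every subject: full-block means
#' for both placebo/CPM series; for offset, the last-6.4 s window of the
#' control series and the T3 window of the offset series.
#'
#' @param traces long data.frame of ratings (columns `subject_id`, `series`,
#'   `time_s`, `vas`) holding both series of every subject.
#' @param timing a [paradigm_timing()].
#' @return a data.frame with columns `subject_id`, `series`, `window_label`,
#'   `block` (1-8) and `mean_vas`.
#' @export
cohort_block_means <- function(traces, timing) {
  traces <- as_trace(traces)
  ids <- unique(traces$subject_id)
  rows <- lapply(ids, function(sid) {
    t1 <- traces[traces$subject_id == sid & traces$series == 1L, , drop = FALSE]
    t2 <- traces[traces$subject_id == sid & traces$series == 2L, , drop = FALSE]
    pair <- windowed_pair(t1, t2, timing)
    rbind(
      data.frame(subject_id = sid, series = 1L,
                 window_label = pair$control$window_label,
                 block = 1:8, mean_vas = pair$control$block_means),
      data.frame(subject_id = sid, series = 2L,
                 window_label = pair$test$window_label,
                 block = 1:8, mean_vas = pair$test$block_means))
  })
  do.call(rbind, rows)
}
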