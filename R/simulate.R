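# Synthetic cohort generator.
#
# No public VAS data accompany the paradigms this package analyses, so the
# generator emulates the statistical structure the analysis assumes: eight
# stimulus blocks per series with paradigm-specific timing, hierarchical
# Gaussian rating noise (a per-block deviation of the block mean plus
# per-sample jitter), and a subject-level modulation effect added to every
# block of the second series. All emitted VAS values are clamped to [0, 100].

#' Specification of a synthetic cohort
#'
#' Bundles everything needed to simulate a cohort reproducibly: size, the
#' true class mix, paradigm, per-class modulation-effect distributions and the
#' rating-noise distributions. Defaults follow the magnitudes observed in
#' placebo-analgesia cohorts: inhibitor effects around -12.4 VAS points,
#' facilitator effects around +13.3, between-block variability (SD of the
#' eight block means) mostly in the 4-12 VAS-point range, and calibrated
#' thermode temperatures on the 44-48.5 degC grid targeting moderate
#' (40-50 VAS) pain.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param class_mix named numeric proportions over
#'   `c(inhibitor, nonresponder, facilitator)`; must sum to 1 (tol 1e-9).
#' @param paradigm `"placebo"`, `"cpm"` or `"offset"`.
#' @param delta_mean,delta_sd named length-3 vectors: mean and SD (VAS points)
#'   of the Gaussian modulation effect added to series 2, per true class.
#'   Negative means inhibition. An SD of 0 gives a point mass.
#' @param block_noise_mean,block_noise_sd mean and spread (VAS points) of the
#'   per-subject between-block noise SD (truncated below at 0.5).
#' @param within_sd_mean,within_sd_sd mean and spread of the per-subject
#'   sample-to-sample jitter SD (truncated below at 0).
#' @param baseline_range VAS interval the moderate-pain baseline is drawn
#'   from, uniformly (calibration targets 40-50).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @examples
#' cohort_spec(20, seed = 1)
#' @export
cohort_spec <- function(n_subjects,
                        class_mix = c(inhibitor = 0.49, nonresponder = 0.34,
                                      facilitator = 0.17),
                        paradigm = c("placebo", "cpm", "offset"),
                        delta_mean = c(inhibitor = -12.4, nonresponder = 0,
                                       facilitator = 13.3),
                        delta_sd = c(inhibitor = 4.8, nonresponder = 0,
                                     facilitator = 7.0),
                        block_noise_mean = 7, block_noise_sd = 2,
                        within_sd_mean = 2, within_sd_sd = 0.5,
                        baseline_range = c(40, 50),
                        seed = 1L) {
  paradigm <- match.arg(paradigm)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 0 ||
      n_subjects != floor(n_subjects)) {
    stop_painmod("`n_subjects` must be a non-negative integer",
                 "painmod_invalid_spec")
  }
  classes <- c("inhibitor", "nonresponder", "facilitator")
  class_mix <- class_mix[classes]
  if (anyNA(class_mix) || abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0)) {
    stop_painmod("`class_mix` must be non-negative proportions over inhibitor/nonresponder/facilitator summing to 1",
                 "painmod_invalid_spec")
  }
  for (v in list(delta_mean, delta_sd)) {
    if (anyNA(v[classes])) {
      stop_painmod("delta distributions must name all three classes",
                   "painmod_invalid_spec")
    }
  }
  if (any(delta_sd[classes] < 0) || block_noise_mean < 0 || within_sd_mean < 0)
    stop_painmod("noise parameters must be non-negative", "painmod_invalid_spec")
  spec <- list(n_subjects = as.integer(n_subjects),
               class_mix = class_mix,
               paradigm = paradigm,
               delta_mean = delta_mean[classes],
               delta_sd = delta_sd[classes],
               block_noise_mean = block_noise_mean,
               block_noise_sd = block_noise_sd,
               within_sd_mean = within_sd_mean,
               within_sd_sd = within_sd_sd,
               baseline_range = baseline_range,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects, paradigm %s, seed %d\n",
              x$n_subjects, x$paradigm, x$seed))
  cat("  class mix:", paste(sprintf("%s %.2f", names(x$class_mix), x$class_mix),
                            collapse = ", "), "\n")
  invisible(x)
}

# Deterministic stratified allocation of class labels by a sequential quota
# rule: subject i gets the class with the largest running deficit
# mix * i - count. Prefix-stable (growing the cohort never relabels earlier
# subjects) and quota-satisfying, so whenever mix * n is integral the counts
# equal mix * n exactly.
allocate_classes <- function(n, mix) {
  if (n == 0L) return(character(0))
  counts <- stats::setNames(numeric(length(mix)), names(mix))
  labels <- character(n)
  for (i in seq_len(n)) {
    deficit <- mix * i - counts
    pick <- names(mix)[which.max(deficit)]
    counts[pick] <- counts[pick] + 1
    labels[i] <- pick
  }
  labels
}

# Questionnaire score ranges (instrument minima/maxima) used for clamping.
questionnaire_ranges <- function() {
  list(lotr = c(0, 24), stai_s = c(20, 80), stai_t = c(20, 80),
       pcs = c(0, 52), bis = c(7, 28), bas = c(13, 52))
}

rclamp <- function(n, mean, sd, range) pmin(range[2], pmax(range[1], stats::rnorm(n, mean, sd)))

# Draw one subject profile. Called inside the subject's own RNG stream.
draw_profile <- function(spec, i, true_class) {
  sid <- sprintf("S%03d", i)
  site <- if (spec$paradigm == "offset") "arm" else sample(c("arm", "face"), 1, prob = c(0.75, 0.25))
  cond_site <- if (spec$paradigm == "cpm") sample(c("arm", "leg"), 1) else "none"
  sex <- sample(c("female", "male"), 1)
  age <- round(max(18, stats::rnorm(1, 26, 6)))
  baseline <- stats::runif(1, spec$baseline_range[1], spec$baseline_range[2])
  delta <- stats::rnorm(1, spec$delta_mean[[true_class]], spec$delta_sd[[true_class]])
  block_noise <- max(0.5, stats::rnorm(1, spec$block_noise_mean, spec$block_noise_sd))
  within_sd <- max(0, stats::rnorm(1, spec$within_sd_mean, spec$within_sd_sd))
  temp_grid <- seq(44, 48.5, by = 0.5)
  temp <- temp_grid[which.min(abs(temp_grid - stats::rnorm(1, 46.8, 0.8)))]
  qr <- questionnaire_ranges()
  # dispositional optimism is mildly class-dependent (inhibitors most
  # optimistic); the other instruments are class-independent covariates
  lotr_mean <- switch(true_class, inhibitor = 15.6, nonresponder = 14.1,
                      facilitator = 12.0)
  quest <- c(lotr = rclamp(1, lotr_mean, 4.4, qr$lotr),
             stai_s = rclamp(1, 35, 8, qr$stai_s),
             stai_t = rclamp(1, 37, 8, qr$stai_t),
             pcs = rclamp(1, 12, 8, qr$pcs),
             bis = rclamp(1, 20, 3.5, qr$bis),
             bas = rclamp(1, 40, 5, qr$bas))
  # 4-decimal quantisation keeps the metadata CSV serialisation lossless
  profile <- list(subject_id = sid, paradigm = spec$paradigm, site = site,
                  conditioning_site = cond_site, sex = sex, age = age,
                  true_class = true_class, baseline_vas = round(baseline, 4),
                  modulation_delta = round(delta, 4),
                  block_noise_sd = round(block_noise, 4),
                  within_block_sd = round(within_sd, 4),
                  calibrated_temp = temp,
                  questionnaires = round(quest, 4))
  class(profile) <- "subject_profile"
  profile
}

#' Construct a subject profile by hand
#'
#' Mostly useful for tests and worked examples; [simulate_cohort()] draws
#' profiles from a [cohort_spec()].
#'
#' @param subject_id identifier.
#' @param paradigm `"placebo"`, `"cpm"` or `"offset"`.
#' @param baseline_vas latent moderate-pain rating (0-100).
#' @param modulation_delta VAS points added to every block of series 2
#'   (negative = inhibition).
#' @param block_noise_sd SD of the per-block deviation of block means.
#' @param within_block_sd SD of sample-to-sample jitter.
#' @param true_class generative class label.
#' @param site,conditioning_site,sex,age,calibrated_temp,questionnaires
#'   covariates stored on the profile.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, paradigm = "placebo",
                            baseline_vas = 45, modulation_delta = 0,
                            block_noise_sd = 5, within_block_sd = 2,
                            true_class = "nonresponder",
                            site = "arm", conditioning_site = "none",
                            sex = "female", age = 25, calibrated_temp = 46.5,
                            questionnaires = NULL) {
  check_finite_numeric(c(baseline_vas, modulation_delta, block_noise_sd,
                         within_block_sd), "profile parameters")
  if (block_noise_sd < 0 || within_block_sd < 0)
    stop_painmod("noise SDs must be non-negative", "painmod_invalid_profile")
  if (!true_class %in% c("inhibitor", "nonresponder", "facilitator"))
    stop_painmod("unknown true_class", "painmod_invalid_profile")
  structure(list(subject_id = as.character(subject_id), paradigm = paradigm,
                 site = site, conditioning_site = conditioning_site, sex = sex,
                 age = age, true_class = true_class, baseline_vas = baseline_vas,
                 modulation_delta = modulation_delta,
                 block_noise_sd = block_noise_sd,
                 within_block_sd = within_block_sd,
                 calibrated_temp = calibrated_temp,
                 questionnaires = questionnaires),
            class = "subject_profile")
}

#' Simulate one continuous VAS rating trace
#'
#' Generates the rating series of one recording. Within each stimulus block
#' the latent level is `baseline_vas` (plus `modulation_delta` if
#' `series_index == 2`) plus a per-block Gaussian deviation with SD
#' `block_noise_sd`; each sample additionally carries Gaussian jitter with SD
#' `within_block_sd`. ISI samples decay linearly to 0 over the first 5 s of
#' the ISI (the ISI temperature is non-painful) and stay at 0. Everything is
#' clamped to the 0-100 VAS range.
#'
#' Sampling is anchored at each segment onset: a segment of duration `d`
#' holds `floor(d / 0.5)` samples at offsets 0, 0.5, ... within the segment.
#' For the 15 s placebo/CPM blocks this is the uniform 0.5 s grid; for the
#' 14.4 s offset blocks it keeps the T1/T2/T3 windows at exactly 8/8/12
#' samples per block.
#'
#' @param profile a [subject_profile()].
#' @param timing a [paradigm_timing()].
#' @param series_index 1 (control series) or 2 (modulated series).
#' @param seed optional integer seed; default derives a stable sub-seed from
#'   the subject id and series.
#' @return an object of class `vas_trace`: a data.frame with columns
#'   `subject_id`, `series`, `time_s`, `vas`.
#' @examples
#' pr <- subject_profile("demo", modulation_delta = -12, block_noise_sd = 4)
#' tr <- simulate_trace(pr, paradigm_timing("placebo"), series_index = 2)
#' range(tr$vas)
#' @export
simulate_trace <- function(profile, timing, series_index, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), inherits(timing, "paradigm_timing"))
  if (!series_index %in% c(1L, 2L))
    stop_painmod("series_index must be 1 or 2", "painmod_invalid_input")
  check_finite_numeric(c(profile$baseline_vas, profile$modulation_delta,
                         profile$block_noise_sd, profile$within_block_sd),
                       "profile parameters")
  if (is.null(seed))
    seed <- subject_seed(0L, paste0(profile$subject_id, "/s", series_index))
  with_seed(seed, {
    dt <- timing$sample_interval
    level <- profile$baseline_vas + if (series_index == 2L) profile$modulation_delta else 0
    n_stim <- samples_per_window(timing$stimulus_duration, dt)
    n_isi <- samples_per_window(timing$isi_duration, dt)
    starts <- block_starts(timing)
    times <- numeric(0); vals <- numeric(0)
    for (k in seq_len(timing$n_blocks)) {
      bdev <- stats::rnorm(1, 0, profile$block_noise_sd)
      latent <- level + bdev
      st <- starts[k] + dt * (seq_len(n_stim) - 1)
      sv <- latent + stats::rnorm(n_stim, 0, profile$within_block_sd)
      it <- starts[k] + timing$stimulus_duration + dt * (seq_len(n_isi) - 1)
      # ratings return to 0 over the first 5 s of the (non-painful) ISI
      decay <- pmax(0, 1 - (it - (starts[k] + timing$stimulus_duration)) / 5)
      iv <- clamp01_100(latent) * decay
      times <- c(times, st, it)
      vals <- c(vals, sv, iv)
    }
    # 4-decimal quantisation (finer than any rating device) keeps the CSV
    # serialisation lossless, so file round-trips reproduce bit-identical
    # downstream numbers
    trace <- data.frame(subject_id = profile$subject_id,
                        series = as.integer(series_index),
                        time_s = round(times, 4),
                        vas = round(clamp01_100(vals), 4))
    class(trace) <- c("vas_trace", "data.frame")
    trace
  })
}

#' Simulate a full cohort
#'
#' Draws class labels by deterministic stratified allocation (largest-remainder
#' rounding of `class_mix * n`), draws each subject's profile and both rating
#' series inside a per-subject RNG stream derived from the spec seed and the
#' subject id, and returns everything downstream stages consume.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `profiles` (list of [subject_profile()]), `traces` (one long data.frame
#'   of both series for all subjects), `metadata` (one row per subject) and
#'   `spec`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(6, seed = 42))
#' table(coh$metadata$true_class)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  timing <- paradigm_timing(spec$paradigm)
  labels <- allocate_classes(spec$n_subjects, spec$class_mix)
  profiles <- vector("list", spec$n_subjects)
  traces <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sid_seed <- subject_seed(spec$seed, sprintf("S%03d", i))
    profiles[[i]] <- with_seed(sid_seed, draw_profile(spec, i, labels[i]))
    t1 <- simulate_trace(profiles[[i]], timing, 1L,
                         seed = subject_seed(spec$seed, sprintf("S%03d/s1", i)))
    t2 <- simulate_trace(profiles[[i]], timing, 2L,
                         seed = subject_seed(spec$seed, sprintf("S%03d/s2", i)))
    traces[[i]] <- rbind(t1, t2)
  }
  metadata <- cohort_metadata(profiles)
  out <- list(profiles = profiles,
              traces = if (spec$n_subjects > 0) do.call(rbind, traces)
                       else empty_trace_df(),
              metadata = metadata,
              spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

empty_trace_df <- function() {
  data.frame(subject_id = character(0), series = integer(0),
             time_s = numeric(0), vas = numeric(0))
}

cohort_metadata <- function(profiles) {
  if (length(profiles) == 0) {
    return(data.frame(subject_id = character(0)))
  }
  rows <- lapply(profiles, function(p) {
    q <- p$questionnaires
    data.frame(subject_id = p$subject_id, paradigm = p$paradigm,
               site = p$site, conditioning_site = p$conditioning_site,
               sex = p$sex, age = p$age, true_class = p$true_class,
               baseline_vas = p$baseline_vas,
               modulation_delta = p$modulation_delta,
               block_noise_sd = p$block_noise_sd,
               within_block_sd = p$within_block_sd,
               calibrated_temp = p$calibrated_temp,
               lotr = unname(q["lotr"]) %||% NA_real_,
               stai_s = unname(q["stai_s"]) %||% NA_real_,
               stai_t = unname(q["stai_t"]) %||% NA_real_,
               pcs = unname(q["pcs"]) %||% NA_real_,
               bis = unname(q["bis"]) %||% NA_real_,
               bas = unname(q["bas"]) %||% NA_real_)
  })
  do.call(rbind, rows)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), seed %d\n",
              x$spec$n_subjects, x$spec$paradigm, x$spec$seed))
  if (x$spec$n_subjects > 0) print(table(x$metadata$true_class))
  invisible(x)
}
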