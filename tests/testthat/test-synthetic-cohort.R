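test_that("zero-noise traces reproduce the latent level exactly, with clamping", {
  tm <- paradigm_timing("placebo")
  pr <- subject_profile("z", baseline_vas = 50, modulation_delta = 0,
                        block_noise_sd = 0, within_block_sd = 0)
  for (s in 1:2) {
    tr <- simulate_trace(pr, tm, s)
    bm <- block_means(tr, tm)
    expect_equal(bm$block_means, rep(50, 8))
    in_block <- tr$time_s %% 30 < 15
    expect_true(all(tr$vas[in_block] == 50))
  }
  pr2 <- subject_profile("c", baseline_vas = 50, modulation_delta = -60,
                         block_noise_sd = 0, within_block_sd = 0)
  tr2 <- simulate_trace(pr2, tm, 2)
  expect_equal(block_means(tr2, tm)$block_means, rep(0, 8))
})

test_that("all emitted VAS values lie in [0, 100]", {
  coh <- simulate_cohort(cohort_spec(12, seed = 101, paradigm = "offset"))
  expect_true(all(coh$traces$vas >= 0 & coh$traces$vas <= 100))
  pr <- subject_profile("hot", baseline_vas = 95, modulation_delta = 20,
                        block_noise_sd = 10, within_block_sd = 5)
  tr <- simulate_trace(pr, paradigm_timing("placebo"), 2)
  expect_true(all(tr$vas <= 100))
})

test_that("non-finite profile parameters are rejected", {
  expect_error(subject_profile("bad", baseline_vas = NaN),
               class = "painmod_invalid_input")
  expect_error(subject_profile("bad", block_noise_sd = -1),
               class = "painmod_invalid_profile")
  pr <- subject_profile("ok")
  expect_error(simulate_trace(pr, paradigm_timing("placebo"), 3),
               class = "painmod_invalid_input")
})

test_that("block-mean variability converges to the noise model's prediction", {
  # oracle: direct resampling of the stated generative law of block means.
  # with between-block SD b and within-sample SD w averaged over 30 samples,
  # block means are iid N(level, sqrt(b^2 + w^2/30)); compare the mean
  # per-series sample SD of 8 block means against that oracle.
  tm <- paradigm_timing("placebo")
  n_rep <- 400
  b <- 5; w <- 3
  pr <- lapply(seq_len(n_rep), function(i)
    subject_profile(paste0("r", i), baseline_vas = 50, block_noise_sd = b,
                    within_block_sd = w))
  sds <- vapply(pr, function(p)
    series_variability(block_means(simulate_trace(p, tm, 1), tm))$sd_of_block_means,
    numeric(1))
  set.seed(424)
  oracle <- mean(replicate(20000, sd(rnorm(8, 0, sqrt(b^2 + w^2 / 30)))))
  # MC error of mean(sds): sd(sds)/sqrt(n_rep) ~ 0.07; allow 4 sigma
  expect_lt(abs(mean(sds) - oracle), 4 * sd(sds) / sqrt(n_rep))
})

test_that("stratified allocation hits the requested class mix deterministically", {
  spec <- cohort_spec(100, class_mix = c(inhibitor = 0.49, nonresponder = 0.34,
                                         facilitator = 0.17), seed = 7)
  coh <- simulate_cohort(spec)
  counts <- table(coh$metadata$true_class)
  expect_equal(unname(counts[c("inhibitor", "nonresponder", "facilitator")]),
               c(49L, 34L, 17L), ignore_attr = TRUE)
})

test_that("cohort simulation is deterministic and order-stable", {
  spec <- cohort_spec(10, seed = 33)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$traces, c2$traces)
  expect_identical(c1$metadata, c2$metadata)
  # adding subjects does not perturb earlier ones (per-subject sub-seeding)
  c3 <- simulate_cohort(cohort_spec(12, seed = 33))
  first10 <- c3$traces[c3$traces$subject_id %in% unique(c1$traces$subject_id), ]
  rownames(first10) <- NULL
  rownames(c1$traces) <- NULL
  expect_identical(c1$traces, first10)
})

test_that("degenerate and invalid cohort specs behave as documented", {
  expect_equal(simulate_cohort(cohort_spec(0, seed = 1))$metadata,
               data.frame(subject_id = character(0)))
  expect_error(cohort_spec(5, class_mix = c(inhibitor = 0.6, nonresponder = 0.6,
                                            facilitator = 0.1)),
               class = "painmod_invalid_spec")
  expect_error(cohort_spec(-1), class = "painmod_invalid_spec")
})

test_that("cohort spec round-trips through JSON and YAML", {
  spec <- cohort_spec(25, seed = 99, paradigm = "cpm",
                      delta_mean = c(inhibitor = -10, nonresponder = 0,
                                     facilitator = 9))
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_cohort_spec(spec, f)
    back <- read_cohort_spec(f)
    expect_equal(unclass(back), unclass(spec))
    unlink(f)
  }
})

test_that("ratings and metadata CSVs round-trip losslessly", {
  coh <- simulate_cohort(cohort_spec(4, seed = 55))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_ratings_csv(coh$traces, f1)
  write_metadata_csv(coh$metadata, f2)
  tr <- read_ratings_csv(f1)
  md <- read_metadata_csv(f2)
  expect_equal(tr$vas, coh$traces$vas)
  expect_equal(tr$time_s, coh$traces$time_s)
  expect_equal(md$lotr, coh$metadata$lotr)
  unlink(c(f1, f2))
})
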