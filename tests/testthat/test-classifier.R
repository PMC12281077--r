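cfg <- bootstrap_config(n_resamples = 10000L, alpha = 0.05, seed = 20)

test_that("bootstrap mean resamples have the stated sampling law", {
  expect_equal(bootstrap_mean_samples(rep(50, 8), 500, seed = 1), rep(50, 500))
  # closed form: P(resampled mean == 0) for (0,...,0,80) is (7/8)^8
  x <- c(0, 0, 0, 0, 0, 0, 0, 80)
  b <- bootstrap_mean_samples(x, 10000, seed = 2)
  p0 <- (7 / 8)^8
  expect_lt(abs(mean(b == 0) - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
  # bootstrap mean is unbiased for the sample mean
  y <- c(12, 35, 47, 51, 58, 63, 70, 88)
  by <- bootstrap_mean_samples(y, 20000, seed = 3)
  expect_lt(abs(mean(by) - mean(y)), 5 * sd(y) / sqrt(8 * 20000))
  expect_error(bootstrap_mean_samples(numeric(0), 10),
               class = "painmod_invalid_input")
})

test_that("degenerate series pairs get the expected labels and p-values", {
  r0 <- classify_subject(rep(50, 8), rep(50, 8), cfg, "same")
  expect_equal(r0$label, "nonresponder")
  expect_equal(r0$p_inhibit, 1)
  expect_equal(r0$p_facilitate, 1)

  r1 <- classify_subject(rep(50, 8), rep(10, 8), cfg, "down")
  expect_equal(r1$label, "inhibitor")
  expect_equal(r1$p_inhibit, 0)
  expect_equal(r1$p_facilitate, 1)

  ctl <- c(42, 44, 46, 48, 50, 52, 54, 56)
  r2 <- classify_subject(ctl, ctl + 15, cfg, "up")
  expect_equal(r2$label, "facilitator")
  # disjoint supports: the exact oracle puts zero mass on the lower tail
  ex <- exact_bootstrap_p(ctl, ctl + 15)
  expect_equal(ex$p_facilitate, 0)
  expect_equal(ex$p_inhibit, 1)
  expect_equal(r2$p_facilitate, 0)
})

test_that("classification rejects malformed input", {
  expect_error(classify_subject(1:7, 1:8, cfg), class = "painmod_invalid_input")
  expect_error(classify_subject(c(1:7, NA), 1:8 + 0, cfg),
               class = "painmod_invalid_input")
})

test_that("exact enumeration matches closed-form cases", {
  ex <- exact_bootstrap_p(rep(50, 8), rep(50, 8))
  expect_equal(ex$p_inhibit, 1)
  expect_equal(ex$p_facilitate, 1)
  # one-off support: test = (0,...,0,80) vs control all 0:
  # diff <= 0 iff the test resample drew no 80, so p_facilitate = (7/8)^8;
  # diff >= 0 always. checked against the enumeration.
  ex2 <- exact_bootstrap_p(rep(0, 8), c(rep(0, 7), 80))
  expect_equal(ex2$p_inhibit, 1)
  expect_equal(ex2$p_facilitate, (7 / 8)^8)
})

test_that("Monte-Carlo p-values sit within binomial error of the exact oracle", {
  set.seed(77)
  n_pairs <- 20
  hits <- 0
  for (i in seq_len(n_pairs)) {
    pair <- draw_block_pair(delta = runif(1, -8, 8), noise_sd = runif(1, 2, 8))
    ex <- exact_bootstrap_p(pair$control, pair$test)
    mc <- classify_subject(pair$control, pair$test,
                           bootstrap_config(10000L, seed = 1000 + i),
                           paste0("pair", i))
    se <- sqrt(ex$p_inhibit * (1 - ex$p_inhibit) / 10000)
    if (abs(mc$p_inhibit - ex$p_inhibit) <= 3 * se + 1e-12) hits <- hits + 1
  }
  expect_gte(hits / n_pairs, 0.95)
})

test_that("inhibitor and facilitator calls are mutually exclusive and exhaustive", {
  set.seed(88)
  for (i in 1:25) {
    pair <- draw_block_pair(delta = runif(1, -20, 20), noise_sd = runif(1, 1, 10))
    r <- classify_subject(pair$control, pair$test,
                          bootstrap_config(2000L, seed = i), paste0("s", i))
    expect_gte(r$p_inhibit + r$p_facilitate, 1)
    expect_false(r$p_inhibit < 0.05 && r$p_facilitate < 0.05)
    expect_true(r$label %in% c("inhibitor", "nonresponder", "facilitator"))
    expect_identical(r$label == "inhibitor", r$p_inhibit < 0.05)
    expect_identical(r$label == "facilitator",
                     r$p_inhibit >= 0.05 && r$p_facilitate < 0.05)
  }
})

test_that("swapping control and test mirrors the tail p-values", {
  # independent streams per argument order: mirror holds exactly for the
  # exact oracle and within Monte-Carlo tolerance for the bootstrap
  set.seed(99)
  for (i in 1:10) {
    pair <- draw_block_pair(delta = runif(1, -10, 10), noise_sd = 5)
    ex_ab <- exact_bootstrap_p(pair$control, pair$test)
    ex_ba <- exact_bootstrap_p(pair$test, pair$control)
    expect_lt(abs(ex_ab$p_inhibit - ex_ba$p_facilitate), 1e-12)
    expect_lt(abs(ex_ab$p_facilitate - ex_ba$p_inhibit), 1e-12)
    mc_ab <- classify_subject(pair$control, pair$test,
                              bootstrap_config(10000L, seed = 7), "s")
    mc_ba <- classify_subject(pair$test, pair$control,
                              bootstrap_config(10000L, seed = 7), "s")
    tol <- 3 * sqrt(0.25 / 10000) * 2 + 0.01
    expect_lt(abs(mc_ab$p_inhibit - mc_ba$p_facilitate), tol)
  }
})

test_that("classification power is monotone in the effect size", {
  # exact-enumeration labels on simulated block means over a delta grid
  set.seed(202)
  deltas <- c(0, -4, -8, -12)
  n_per <- 150
  rate <- vapply(deltas, function(d) {
    hits <- 0
    for (i in seq_len(n_per)) {
      pair <- draw_block_pair(delta = d, noise_sd = 4)
      ex <- exact_bootstrap_p(pair$control, pair$test)
      if (ex$p_inhibit < 0.05) hits <- hits + 1
    }
    hits / n_per
  }, numeric(1))
  expect_true(all(diff(rate) >= -0.05))
  expect_gt(rate[4], rate[1])
})

test_that("cohort classification is order-invariant and checks ids", {
  set.seed(303)
  pairs <- lapply(1:6, function(i) draw_block_pair(delta = c(-15, 0, 15)[i %% 3 + 1]))
  names(pairs) <- paste0("P", 1:6)
  cc1 <- classify_cohort(pairs, cfg)
  cc2 <- classify_cohort(rev(pairs), cfg)
  r2 <- cc2$results[match(cc1$results$subject_id, cc2$results$subject_id), ]
  rownames(r2) <- NULL
  expect_equal(cc1$results, r2)
  expect_equal(sum(cc1$proportions$percent), 100)
  dup <- pairs; names(dup) <- rep("P1", 6)
  expect_error(classify_cohort(dup, cfg), class = "painmod_duplicate_subject")
})

test_that("a cohort of identical null subjects is all nonresponders", {
  pairs <- lapply(1:10, function(i) list(control = rep(45, 8), test = rep(45, 8)))
  names(pairs) <- paste0("N", 1:10)
  cc <- classify_cohort(pairs, cfg)
  expect_true(all(cc$results$label == "nonresponder"))
  expect_equal(cc$proportions$percent, c(0, 100, 0))
})
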