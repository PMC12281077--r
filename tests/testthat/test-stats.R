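test_that("paired effect summaries reproduce published-scale worked examples", {
  # rows recomputable from their printed n / mean / SD triples
  rows <- list(
    list(n = 77, m = -3.48, s = 11.26, d = 0.31, t = -2.71),   # placebo arm
    list(n = 23, m = -4.38, s = 9.31, d = 0.47, t = -2.26),    # placebo face
    list(n = 10, m = -13.02, s = 5.36, d = 2.43, t = -7.68),   # placebo inh face
    list(n = 34, m = 0.41, s = 3.75, d = 0.11, t = 0.64),      # placebo nonresp
    list(n = 17, m = 13.27, s = 6.98, d = 1.90, t = 7.84),     # placebo facil
    list(n = 135, m = -2.89, s = 11.75, d = 0.25, t = -2.86),  # cpm main
    list(n = 12, m = -21.39, s = 10.79, d = 1.98, t = -6.87),  # offset inh
    list(n = 7, m = 20.40, s = 11.89, d = 1.72, t = 4.54))     # offset facil
  for (r in rows) {
    es <- paired_effect(prescribed_diffs(r$n, r$m, r$s, seed = 1))
    expect_equal(es$n, r$n)
    expect_equal(es$mean_diff, r$m, tolerance = 1e-9)
    expect_equal(es$sd_diff, r$s, tolerance = 1e-9)
    expect_equal(round(es$cohens_d, 2), r$d)
    expect_equal(round(es$t_value, 2), r$t)
    expect_equal(es$df, r$n - 1)
  }
})

test_that("paired effect handles symmetric and degenerate inputs", {
  es <- paired_effect(c(1, -1))
  expect_equal(es$mean_diff, 0)
  expect_equal(es$cohens_d, 0)
  expect_equal(es$t_value, 0)
  deg <- paired_effect(rep(3, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t_value))
  expect_error(paired_effect(5), class = "painmod_invalid_input")
})

test_that("paired t agrees with a textbook oracle to 1e-12", {
  set.seed(11)
  for (i in 1:20) {
    d <- rnorm(sample(5:50, 1), mean = runif(1, -10, 10), sd = runif(1, 1, 15))
    es <- paired_effect(d)
    n <- length(d)
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(es$t_value, t_oracle, tolerance = 1e-12)
    expect_equal(es$p_value, 2 * pt(-abs(t_oracle), n - 1), tolerance = 1e-12)
    expect_equal(sign(es$t_value), sign(es$mean_diff))
    # agreement with the built-in one-sample t as an independent route
    expect_equal(es$t_value, unname(t.test(d)$statistic), tolerance = 1e-12)
  }
})

test_that("percent change is the per-subject ratio, averaged with SEM", {
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(50, 25), -50)
  expect_error(percent_change(0, 10), class = "painmod_invalid_input")
  set.seed(22)
  ctl <- runif(30, 30, 60); tst <- runif(30, 10, 80)
  pc <- percent_change(ctl, tst)
  # brute-force loop oracle
  pc_o <- numeric(30)
  for (i in 1:30) pc_o[i] <- 100 * (tst[i] - ctl[i]) / ctl[i]
  expect_equal(pc, pc_o)
  ms <- mean_sem(pc)
  expect_equal(ms$mean, sum(pc_o) / 30)
  expect_equal(ms$sem, sd(pc_o) / sqrt(30))
})

test_that("pooled two-proportion z matches the formula oracle and is antisymmetric", {
  r <- two_proportion_test(10, 100, 10, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  r2 <- two_proportion_test(49, 100, 32, 135)
  expect_equal(r2$z, oracle_two_prop_z(49, 100, 32, 135), tolerance = 1e-12)
  # cross-check against the uncorrected chi-square route: X^2 = z^2
  ct <- suppressWarnings(prop.test(c(49, 32), c(100, 135), correct = FALSE))
  expect_equal(r2$z^2, unname(ct$statistic), tolerance = 1e-10)
  r3 <- two_proportion_test(32, 135, 49, 100)
  expect_equal(r3$z, -r2$z, tolerance = 1e-12)
  expect_equal(r3$p, r2$p, tolerance = 1e-12)
  expect_equal(two_proportion_test(0, 50, 0, 60), list(z = 0, p = 1))
  expect_error(two_proportion_test(5, 0, 1, 10), class = "painmod_invalid_input")
})

test_that("the normality gate routes clean and pathological samples correctly", {
  set.seed(33)
  normal_groups <- list(a = rnorm(500), b = rnorm(500, 5, 2))
  expect_equal(normality_gate(normal_groups)$test, "t_test")
  # two point masses: maximal distance from any fitted normal
  bimodal <- list(a = c(rep(0, 40), rep(10, 40)), b = rnorm(80))
  expect_equal(normality_gate(bimodal)$test, "mann_whitney")
  # degenerate and tiny groups force the rank branch
  expect_equal(normality_gate(list(a = rep(1, 10), b = rnorm(10)))$test,
               "mann_whitney")
  expect_equal(normality_gate(list(a = rnorm(4), b = rnorm(100)))$test,
               "mann_whitney")
})

test_that("pairwise comparisons are Bonferroni-capped and detect known offsets", {
  set.seed(44)
  same <- rnorm(40)
  identical3 <- list(i = same, n = same, f = same)
  cg <- compare_groups(identical3, measure = "m")
  expect_true(all(cg$raw_p == 1))
  expect_true(all(cg$bonferroni_p == 1))
  expect_true(all(cg$bonferroni_p <= 1))
  groups <- list(i = rnorm(40, 0), n = rnorm(40, 0.2), f = rnorm(40, 3))
  cg2 <- compare_groups(groups, measure = "m")
  expect_equal(nrow(cg2), 3)
  expect_equal(cg2$bonferroni_p, pmin(1, cg2$raw_p * 3))
  if (all(cg2$test == "t_test")) {
    # i vs f must be detected, consistent with the two-sample t oracle
    tt <- t.test(groups$i, groups$f, var.equal = TRUE)
    row <- cg2[cg2$group1 == "i" & cg2$group2 == "f", ]
    expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_lt(row$bonferroni_p, 0.05)
  }
  w <- capture_warnings(compare_groups(list(a = rnorm(10), b = 1, c = rnorm(10))))
  expect_true(any(grepl("n < 2", w)))
})

test_that("one-way ANOVA behaves classically, including F = t^2 on two groups", {
  g3 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  a0 <- anova_with_posthoc(g3)
  expect_equal(a0$F, 0)
  expect_equal(a0$df_between, 2)
  expect_equal(a0$df_within, 6)
  set.seed(55)
  g2 <- list(a = rnorm(15, 0), b = rnorm(12, 1.5))
  a2 <- anova_with_posthoc(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
  # hand-enumerable degenerate decomposition: within-SS 0, between-SS > 0
  deg <- anova_with_posthoc(list(a = c(0, 0), b = c(1, 1), c = c(2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$F, Inf)
  # three groups with a real effect run post hoc t-tests
  g4 <- list(i = rnorm(20, 0), n = rnorm(20, 0), f = rnorm(20, 4))
  a4 <- anova_with_posthoc(g4)
  if (a4$p < 0.05) {
    expect_equal(nrow(a4$posthoc), 3)
    row <- a4$posthoc[a4$posthoc$group1 == "i" & a4$posthoc$group2 == "f", ]
    expect_equal(row$t, unname(t.test(g4$i, g4$f, var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(anova_with_posthoc(list(a = 1, b = c(1, 2))),
               class = "painmod_invalid_input")
})
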