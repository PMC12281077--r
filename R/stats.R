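# Group-level statistics: paired effect sizes, percent pain change,
# two-proportion tests, normality-gated pairwise comparisons with Bonferroni
# correction, and one-way ANOVA with post hoc t-tests.

#' Paired effect summary of within-subject VAS differences
#'
#' For a vector of per-subject differences (series 2 minus series 1)
#' computes the mean, sample SD (n - 1), the paired Cohen's D
#' `|mean| / sd`, the paired t statistic `mean / (sd / sqrt(n))` and its
#' two-sided p-value on n - 1 degrees of freedom.
#'
#' @param diffs numeric vector of within-subject differences (n >= 2).
#' @param group optional label carried on the result.
#' @return an object of class `effect_summary` with fields `group`, `n`,
#'   `mean_diff`, `sd_diff`, `cohens_d`, `t_value`, `df`, `p_value` and
#'   `degenerate` (TRUE when `sd_diff == 0`, in which case D/t/p are NA).
#' @examples
#' es <- paired_effect(c(-10, -14, -12, -13, -11, -15, -12, -13))
#' es$cohens_d
#' @export
paired_effect <- function(diffs, group = "all") {
  check_finite_numeric(diffs, "diffs")
  n <- length(diffs)
  if (n < 2) stop_painmod("need at least 2 differences", "painmod_invalid_input")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  degenerate <- s == 0
  if (degenerate) {
    d <- NA_real_; t_val <- NA_real_; p <- NA_real_
  } else {
    d <- abs(m) / s
    t_val <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_val), df = n - 1)
  }
  structure(list(group = group, n = n, mean_diff = m, sd_diff = s,
                 cohens_d = d, t_value = t_val, df = n - 1, p_value = p,
                 degenerate = degenerate),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<effect_summary> %s (n = %d): mean %.2f, SD 0 - degenerate (t undefined)\n",
                x$group, x$n, x$mean_diff))
  } else {
    cat(sprintf("<effect_summary> %s (n = %d): mean %.2f, SD %.2f, D = %.2f, t(%d) = %.2f, p = %.3g\n",
                x$group, x$n, x$mean_diff, x$sd_diff, x$cohens_d, x$df,
                x$t_value, x$p_value))
  }
  invisible(x)
}

#' Difference vector with a prescribed mean and SD
#'
#' Emits `n` values whose sample mean and sample SD (n - 1 denominator)
#' equal `mean` and `sd` exactly, by standardising a Gaussian draw. Useful
#' for recomputing paired effect statistics from a published n / mean / SD
#' triple, since the paired t and Cohen's D depend on the differences only
#' through those moments.
#'
#' @param n number of values (>= 2).
#' @param mean,sd target sample mean and SD (`sd >= 0`).
#' @param seed RNG seed for the underlying draw.
#' @return numeric vector of length `n`.
#' @examples
#' d <- prescribed_diffs(12, -21.39, 10.79, seed = 1)
#' c(mean(d), sd(d))
#' @export
prescribed_diffs <- function(n, mean, sd, seed = 1L) {
  if (n < 2) stop_painmod("need n >= 2", "painmod_invalid_input")
  if (sd < 0) stop_painmod("sd must be >= 0", "painmod_invalid_input")
  if (sd == 0) return(rep(mean, n))
  with_seed(seed, {
    z <- stats::rnorm(n)
    z <- (z - base::mean(z)) / stats::sd(z)
    mean + sd * z
  })
}

#' Percent pain change
#'
#' `100 * (test - control) / control`, the per-subject percent change in
#' mean pain; undefined when the control mean is not positive.
#'
#' @param control_mean,test_mean mean VAS of the control and modulated series
#'   (vectorised; recycled pairwise).
#' @return percent change, same length as the inputs.
#' @examples
#' percent_change(50, 25)  # -50
#' @export
percent_change <- function(control_mean, test_mean) {
  check_finite_numeric(control_mean, "control_mean")
  check_finite_numeric(test_mean, "test_mean")
  if (any(control_mean <= 0))
    stop_painmod("percent change undefined for control mean <= 0",
                 "painmod_invalid_input")
  100 * (test_mean - control_mean) / control_mean
}

#' Mean and SEM of a vector
#' @param x numeric vector.
#' @return list with `mean`, `sem`, `n`.
#' @export
mean_sem <- function(x) {
  check_finite_numeric(x, "x")
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}

#' Two independent population proportions test
#'
#' Pooled two-proportion z test: `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))`
#' with `p` the pooled proportion; two-sided p from the standard normal.
#' When the pooled proportion is 0 or 1 both samples are unanimous and
#' identical in rate, so `z = 0, p = 1` by convention.
#'
#' @param k1,n1 successes and size of sample 1.
#' @param k2,n2 successes and size of sample 2.
#' @return list with `z` and `p`.
#' @examples
#' two_proportion_test(49, 100, 32, 135)
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop_painmod("sample sizes must be >= 1", "painmod_invalid_input")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop_painmod("counts must satisfy 0 <= k <= n", "painmod_invalid_input")
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool == 0 || pool == 1) return(list(z = 0, p = 1))
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Normality gate for a family of group comparisons
#'
#' Tests each group against a normal law with the sample's own mean and SD
#' (Lilliefors-corrected Kolmogorov-Smirnov, via [nortest::lillie.test()]).
#' If any group departs from normality at 0.05 the pairwise comparisons use
#' the Mann-Whitney U test; otherwise the two-sample t-test. Groups that are
#' degenerate (zero variance) or too small for the Lilliefors test (n < 5)
#' force the Mann-Whitney branch.
#'
#' @param groups named list of numeric vectors.
#' @return list with `test` (`"t_test"` or `"mann_whitney"`) and
#'   `normality_p` (named vector, NA where the test was not applicable).
#' @export
normality_gate <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  ps <- vapply(groups, function(g) {
    if (length(g) < 5 || stats::sd(g) == 0) return(NA_real_)
    nortest::lillie.test(g)$p.value
  }, numeric(1))
  nonnormal <- any(is.na(ps)) || any(ps < 0.05)
  list(test = if (nonnormal) "mann_whitney" else "t_test", normality_p = ps)
}

#' Pairwise group comparisons with a normality gate and Bonferroni correction
#'
#' All pairwise comparisons of one measure among the response groups. The
#' test statistic is chosen by [normality_gate()] over the full family of
#' groups; raw p-values are Bonferroni-corrected with the family size
#' `m = number of pairwise comparisons` (3 for three groups).
#'
#' @param groups named list of numeric vectors (one per response class).
#' @param measure label carried on the results.
#' @param family_size Bonferroni multiplier; defaults to the number of pairs.
#' @param var_equal use the pooled-variance two-sample t (default); set
#'   `FALSE` for Welch.
#' @return data.frame with one row per compared pair: `measure`, `group1`,
#'   `group2`, `test`, `statistic`, `raw_p`, `bonferroni_p`. Pairs where a
#'   group has n < 2 are skipped with a warning.
#' @export
compare_groups <- function(groups, measure = "measure", family_size = NULL,
                           var_equal = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pair_idx <- utils::combn(length(groups), 2)
  m <- family_size %||% ncol(pair_idx)
  gate <- normality_gate(groups)
  rows <- list()
  for (j in seq_len(ncol(pair_idx))) {
    i1 <- pair_idx[1, j]; i2 <- pair_idx[2, j]
    g1 <- groups[[i1]]; g2 <- groups[[i2]]
    if (length(g1) < 2 || length(g2) < 2) {
      warning(sprintf("skipping %s vs %s: group with n < 2",
                      names(groups)[i1], names(groups)[i2]))
      next
    }
    if (gate$test == "t_test") {
      tt <- stats::t.test(g1, g2, var.equal = var_equal)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(g1, g2))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    rows[[j]] <- data.frame(measure = measure,
                            group1 = names(groups)[i1],
                            group2 = names(groups)[i2],
                            test = gate$test, statistic = stat, raw_p = p,
                            bonferroni_p = min(1, p * m))
  }
  do.call(rbind, rows)
}

#' One-way ANOVA with post hoc two-sample t-tests
#'
#' Single-factor fixed-effects ANOVA across the response groups; when the
#' main effect is significant at 0.05, all pairwise pooled-variance
#' two-sample t-tests are run, uncorrected.
#'
#' @param groups named list of numeric vectors, one per group (each n >= 2).
#' @param measure label carried on the result.
#' @return an object of class `anova_result`: list with `measure`, `F`,
#'   `df_between`, `df_within`, `p`, `posthoc` (data.frame or NULL) and
#'   `degenerate` (TRUE when the within-group variance is zero everywhere,
#'   making F unbounded).
#' @export
anova_with_posthoc <- function(groups, measure = "measure") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2))
    stop_painmod("every group needs n >= 2", "painmod_invalid_input")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  k <- length(groups); N <- length(values)
  within_ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  degenerate <- within_ss == 0
  if (degenerate) {
    between_var <- stats::var(vapply(groups, mean, 1))
    if (between_var > 0) { F_val <- Inf; p <- 0 } else { F_val <- 0; p <- 1 }
  } else {
    fit <- stats::aov(values ~ g)
    tab <- summary(fit)[[1]]
    F_val <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  posthoc <- NULL
  if (!is.na(p) && p < 0.05) {
    pair_idx <- utils::combn(k, 2)
    rows <- lapply(seq_len(ncol(pair_idx)), function(j) {
      g1 <- groups[[pair_idx[1, j]]]; g2 <- groups[[pair_idx[2, j]]]
      if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
        data.frame(group1 = names(groups)[pair_idx[1, j]],
                   group2 = names(groups)[pair_idx[2, j]],
                   t = if (mean(g1) == mean(g2)) 0 else Inf * sign(mean(g1) - mean(g2)),
                   p = if (mean(g1) == mean(g2)) 1 else 0)
      } else {
        tt <- stats::t.test(g1, g2, var.equal = TRUE)
        data.frame(group1 = names(groups)[pair_idx[1, j]],
                   group2 = names(groups)[pair_idx[2, j]],
                   t = unname(tt$statistic), p = tt$p.value)
      }
    })
    posthoc <- do.call(rbind, rows)
  }
  structure(list(measure = measure, F = F_val, df_between = k - 1,
                 df_within = N - k, p = p, posthoc = posthoc,
                 degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s: F(%d, %d) = %s, p = %s%s\n", x$measure,
              x$df_between, x$df_within, format(x$F, digits = 4),
              format(x$p, digits = 3),
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  if (!is.null(x$posthoc)) {
    cat("post hoc two-sample t-tests (uncorrected):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
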