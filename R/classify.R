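# Bootstrapped responder classification.
#
# Each recording series yields eight block-mean VAS values. The test draws
# B bootstrap resamples of the mean from each series independently (8 draws
# with replacement per resample), pairs the two streams by replicate index,
# and reads one-tailed p-values off the tail proportions of the paired
# differences. A subject whose second series is significantly lower is an
# inhibitor, significantly higher a facilitator, otherwise a nonresponder.

#' Bootstrap test configuration
#'
#' @param n_resamples number of bootstrap resamples per series (default 10000).
#' @param alpha one-tailed significance level (default 0.05; must be in
#'   (0, 0.5) so the inhibitor and facilitator calls are mutually exclusive).
#' @param seed master integer seed; per-subject streams are derived from it.
#' @return an object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 10000L, alpha = 0.05, seed = 1L) {
  if (n_resamples < 1) stop_painmod("n_resamples must be >= 1", "painmod_invalid_config")
  if (alpha <= 0 || alpha >= 0.5)
    stop_painmod("alpha must lie in (0, 0.5)", "painmod_invalid_config")
  structure(list(n_resamples = as.integer(n_resamples), alpha = alpha,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Bootstrap resamples of the mean of eight block means
#'
#' Draws `n_resamples` means, each over 8 draws with replacement from the
#' input block means.
#'
#' @param block_means numeric vector of exactly 8 values.
#' @param n_resamples number of resampled means.
#' @param seed optional seed for a local RNG stream; `NULL` uses the current
#'   stream.
#' @return numeric vector of `n_resamples` resampled means.
#' @examples
#' b <- bootstrap_mean_samples(c(40, 42, 44, 46, 48, 50, 52, 54), 1000, seed = 7)
#' mean(b)  # close to mean(block_means)
#' @export
bootstrap_mean_samples <- function(block_means, n_resamples, seed = NULL) {
  check_finite_numeric(block_means, "block_means", len = 8L)
  draw <- function() {
    idx <- sample.int(8L, 8L * n_resamples, replace = TRUE)
    rowMeans(matrix(block_means[idx], nrow = n_resamples, ncol = 8L))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

new_classification <- function(subject_id, p_inhibit, p_facilitate, mean_diff,
                               config, method) {
  label <- if (p_inhibit < config$alpha) "inhibitor"
           else if (p_facilitate < config$alpha) "facilitator"
           else "nonresponder"
  structure(list(subject_id = subject_id, label = label,
                 p_inhibit = p_inhibit, p_facilitate = p_facilitate,
                 mean_diff = mean_diff, method = method, config = config),
            class = "pain_classification")
}

#' @export
print.pain_classification <- function(x, ...) {
  cat(sprintf("<pain_classification> %s: %s (mean diff %.2f VAS; p_inhibit %.4f, p_facilitate %.4f, %s)\n",
              x$subject_id, x$label, x$mean_diff, x$p_inhibit, x$p_facilitate,
              x$method))
  invisible(x)
}

series_values <- function(x, name) {
  v <- if (inherits(x, "block_series")) x$block_means else x
  check_finite_numeric(v, name, len = 8L)
  v
}

#' Classify one subject as inhibitor, nonresponder or facilitator
#'
#' Draws `n_resamples` bootstrap means independently from the control and
#' test series, pairs them by replicate index, and forms the paired
#' differences `d_b = test_mean_b - control_mean_b`. The one-tailed p-values
#' are the tail proportions `p_inhibit = #(d_b >= 0) / B` and
#' `p_facilitate = #(d_b <= 0) / B`; ties at zero count toward both tails,
#' so two identical constant series give `p = 1` on both sides and the
#' degenerate label is nonresponder. The label is inhibitor when
#' `p_inhibit < alpha`, facilitator when `p_facilitate < alpha`, otherwise
#' nonresponder; with `alpha < 0.5` the two calls are mutually exclusive
#' because the two p-values sum to at least 1.
#'
#' @param control series-1 block means (a `block_series` or 8 values).
#' @param test series-2 block means (same form).
#' @param config a [bootstrap_config()].
#' @param subject_id identifier recorded on the result (defaults to the
#'   control series' id if available).
#' @return a `pain_classification` object.
#' @examples
#' cfg <- bootstrap_config(seed = 11)
#' classify_subject(rep(50, 8), rep(10, 8), cfg, "sub1")$label  # "inhibitor"
#' @export
classify_subject <- function(control, test, config = bootstrap_config(),
                             subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- if (inherits(control, "block_series")) control$subject_id else "subject"
  c_v <- series_values(control, "control")
  t_v <- series_values(test, "test")
  if (inherits(control, "block_series") && inherits(test, "block_series") &&
      !identical(control$subject_id, test$subject_id))
    stop_painmod("control and test series belong to different subjects",
                 "painmod_invalid_input")
  seed <- subject_seed(config$seed, subject_id)
  with_seed(seed, {
    B <- config$n_resamples
    mc <- bootstrap_mean_samples(c_v, B)
    mt <- bootstrap_mean_samples(t_v, B)
    d <- mt - mc
    p_inh <- mean(d >= 0)
    p_fac <- mean(d <= 0)
    new_classification(subject_id, p_inh, p_fac, mean(t_v) - mean(c_v),
                       config, method = "bootstrap")
  })
}

# ---- exact enumeration oracle -----------------------------------------------

# All compositions of `total` indistinguishable draws into `cells` cells:
# every possible multiset of 8 draws-with-replacement from 8 values, as a
# C(15,7) x 8 count matrix. Cached after first use.
compositions_memo <- new.env(parent = emptyenv())

enumerate_compositions <- function(total = 8L, cells = 8L) {
  key <- paste(total, cells, sep = "_")
  if (!is.null(compositions_memo[[key]])) return(compositions_memo[[key]])
  rec <- function(rest, ncell) {
    if (ncell == 1L) return(matrix(rest, nrow = 1L))
    do.call(rbind, lapply(0:rest, function(k) cbind(k, rec(rest - k, ncell - 1L))))
  }
  m <- rec(total, cells)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  compositions_memo[[key]] <- m
  m
}

# Multinomial probability of each composition under uniform draws:
# (8! / prod(k_i!)) / 8^8.
composition_weights <- function(comp) {
  total <- sum(comp[1L, ])
  cells <- ncol(comp)
  logw <- lfactorial(total) - rowSums(lfactorial(comp)) - total * log(cells)
  exp(logw)
}

# Distribution of the bootstrap mean of 8 draws from `x`: all achievable
# means with exact multinomial probabilities. Sums are rounded to 9 decimals
# so that identical rational means compare equal across the two series.
bootstrap_mean_distribution <- function(x) {
  comp <- enumerate_compositions(8L, 8L)
  sums <- round(as.numeric(comp %*% x), 9)
  list(mean = sums / 8, w = composition_weights(comp))
}

#' Exact bootstrap p-values by full enumeration
#'
#' Enumerates every multiset of 8 draws with replacement from each series
#' (6435 compositions per series) with its multinomial probability, and
#' returns the exact probabilities `P(test_mean - control_mean >= 0)` and
#' `P(test_mean - control_mean <= 0)` under independent pairing. This is the
#' population limit of the Monte-Carlo test in [classify_subject()] as the
#' number of resamples grows, and serves as its verification oracle.
#'
#' @param control,test 8 block means each (`block_series` or numeric).
#' @return a list with `p_inhibit` and `p_facilitate` (exact probabilities).
#' @examples
#' exact_bootstrap_p(rep(50, 8), rep(50, 8))  # both 1
#' @export
exact_bootstrap_p <- function(control, test) {
  c_v <- series_values(control, "control")
  t_v <- series_values(test, "test")
  dc <- bootstrap_mean_distribution(c_v)
  dt_ <- bootstrap_mean_distribution(t_v)
  ord <- order(dc$mean)
  cm <- dc$mean[ord]
  cw <- cumsum(dc$w[ord])
  n <- length(cm)
  # P(c <= t) per test mean: count of control means <= t (ties included)
  le_idx <- findInterval(dt_$mean, cm)
  p_le <- ifelse(le_idx == 0, 0, cw[pmax(le_idx, 1L)])
  # P(c < t): strict inequality
  lt_idx <- findInterval(dt_$mean, cm, left.open = TRUE)
  p_lt <- ifelse(lt_idx == 0, 0, cw[pmax(lt_idx, 1L)])
  # clamp away accumulated floating error in the multinomial weights
  list(p_inhibit = min(1, max(0, sum(dt_$w * p_le))),       # P(c <= t)
       p_facilitate = min(1, max(0, sum(dt_$w * (1 - p_lt)))))  # P(c >= t)
}

# Exact-enumeration classification (same labelling rule as the bootstrap).
classify_subject_exact <- function(control, test, config = bootstrap_config(),
                                   subject_id = "subject") {
  p <- exact_bootstrap_p(control, test)
  c_v <- series_values(control, "control")
  t_v <- series_values(test, "test")
  new_classification(subject_id, p$p_inhibit, p$p_facilitate,
                     mean(t_v) - mean(c_v), config, method = "exact")
}

# ---- cohort level -----------------------------------------------------------

#' Classify every subject of a cohort
#'
#' Runs [classify_subject()] on each subject's windowed series pair and
#' summarises the cohort: counts and percentages of inhibitors,
#' nonresponders and facilitators, overall and stratified by test site and
#' sex when a metadata table is supplied.
#'
#' @param pairs either a named list of `list(control =, test =)` series
#'   pairs, or a block-means data.frame as produced by
#'   [cohort_block_means()] (columns `subject_id`, `series`, `block`,
#'   `mean_vas`).
#' @param config a [bootstrap_config()]; each subject gets a sub-seeded
#'   stream derived from `config$seed` and its id, so results do not depend
#'   on cohort order.
#' @param metadata optional data.frame with `subject_id`, `site`, `sex`
#'   columns for stratified proportions.
#' @return an object of class `cohort_classification`: list with `results`
#'   (data.frame: subject_id, label, p_inhibit, p_facilitate, mean_diff,
#'   n_resamples, seed), `proportions` (label, n, percent), `strata`
#'   (stratified proportions or NULL) and `config`.
#' @export
classify_cohort <- function(pairs, config = bootstrap_config(), metadata = NULL) {
  pairs <- normalise_pairs(pairs)
  if (length(pairs) < 1)
    stop_painmod("cohort must contain at least one subject", "painmod_invalid_input")
  ids <- names(pairs)
  if (anyDuplicated(ids))
    stop_painmod("duplicate subject_id in cohort", "painmod_duplicate_subject")
  rows <- lapply(ids, function(sid) {
    r <- classify_subject(pairs[[sid]]$control, pairs[[sid]]$test, config, sid)
    data.frame(subject_id = sid, label = r$label, p_inhibit = r$p_inhibit,
               p_facilitate = r$p_facilitate, mean_diff = r$mean_diff,
               n_resamples = config$n_resamples, seed = config$seed)
  })
  results <- do.call(rbind, rows)
  out <- list(results = results,
              proportions = label_proportions(results$label),
              strata = stratified_proportions(results, metadata),
              config = config)
  class(out) <- "cohort_classification"
  out
}

label_levels <- c("inhibitor", "nonresponder", "facilitator")

label_proportions <- function(labels) {
  tab <- table(factor(labels, levels = label_levels))
  data.frame(label = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(labels))
}

stratified_proportions <- function(results, metadata) {
  if (is.null(metadata)) return(NULL)
  md <- merge(results[, c("subject_id", "label")], metadata, by = "subject_id")
  strat <- list()
  for (var in intersect(c("site", "sex"), names(md))) {
    for (lev in unique(md[[var]])) {
      sub <- md[md[[var]] == lev, ]
      p <- label_proportions(sub$label)
      p$stratum <- paste0(var, "=", lev)
      strat[[paste0(var, "_", lev)]] <- p
    }
  }
  if (length(strat) == 0) NULL else do.call(rbind, strat)
}

# Accept either the list-of-pairs form or a long block-means data.frame.
normalise_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    req <- c("subject_id", "series", "block", "mean_vas")
    if (!all(req %in% names(pairs)))
      stop_painmod("block-means table needs columns subject_id, series, block, mean_vas",
                   "painmod_invalid_input")
    ids <- unique(pairs$subject_id)
    out <- lapply(ids, function(sid) {
      s1 <- pairs[pairs$subject_id == sid & pairs$series == 1L, ]
      s2 <- pairs[pairs$subject_id == sid & pairs$series == 2L, ]
      list(control = s1$mean_vas[order(s1$block)],
           test = s2$mean_vas[order(s2$block)])
    })
    names(out) <- ids
    return(out)
  }
  if (!is.list(pairs))
    stop_painmod("pairs must be a list or a block-means data.frame",
                 "painmod_invalid_input")
  if (is.null(names(pairs)))
    names(pairs) <- sprintf("S%03d", seq_along(pairs))
  pairs
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("<cohort_classification> %d subjects, B = %d, alpha = %.3f (one-tailed)\n",
              nrow(x$results), x$config$n_resamples, x$config$alpha))
  print(x$proportions, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cohort_classification <- function(object, ...) {
  cat(sprintf("Bootstrap responder classification of %d subjects\n", nrow(object$results)))
  cat(sprintf("  %d resamples per series, one-tailed alpha = %.3f, seed %d\n",
              object$config$n_resamples, object$config$alpha, object$config$seed))
  print(object$proportions, row.names = FALSE)
  if (!is.null(object$strata)) {
    cat("Stratified proportions:\n")
    print(object$strata, row.names = FALSE)
  }
  cat(sprintf("Mean VAS change (series 2 - series 1): %.2f (range %.2f to %.2f)\n",
              mean(object$results$mean_diff), min(object$results$mean_diff),
              max(object$results$mean_diff)))
  invisible(object)
}

#' @export
plot.cohort_classification <- function(x, ...) {
  p <- x$proportions
  graphics::barplot(stats::setNames(p$percent, p$label),
                    ylab = "% of cohort", ylim = c(0, 100),
                    main = "Responder classification", ...)
  invisible(x)
}
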