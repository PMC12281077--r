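# End-to-end orchestration: simulate (or ingest) -> block means -> classify
# -> group statistics -> files + machine-readable report.

#' Run configuration for the full pipeline
#'
#' @param mode `"simulate"` (generate a cohort from `spec`) or `"ingest"`
#'   (read `ratings_csv` / `metadata_csv`).
#' @param spec a [cohort_spec()] (simulate mode only).
#' @param ratings_csv,metadata_csv input paths (ingest mode only;
#'   `metadata_csv` optional).
#' @param paradigm paradigm of ingested data (ignored in simulate mode,
#'   where the spec carries it).
#' @param bootstrap a [bootstrap_config()].
#' @param out_dir output directory for CSV artefacts and the JSON report;
#'   `NULL` keeps everything in memory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"), spec = NULL,
                       ratings_csv = NULL, metadata_csv = NULL,
                       paradigm = NULL, bootstrap = bootstrap_config(),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(spec) || !is.null(ratings_csv))
      stop_painmod("simulate mode requires `spec` and no input paths",
                   "painmod_invalid_config")
  } else {
    if (is.null(ratings_csv) || !is.null(spec))
      stop_painmod("ingest mode requires `ratings_csv` and no `spec`",
                   "painmod_invalid_config")
    if (is.null(paradigm))
      stop_painmod("ingest mode requires `paradigm`", "painmod_invalid_config")
  }
  structure(list(mode = mode, spec = spec, ratings_csv = ratings_csv,
                 metadata_csv = metadata_csv, paradigm = paradigm,
                 bootstrap = bootstrap, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", string_hash(as.character(s)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — obtain ratings (simulate or ingest),
#' reduce to block means with the paradigm's analysis windows, classify
#' every subject with the bootstrap test, and compute the cohort statistics:
#' label proportions, paired effect summaries by group and site, percent
#' pain change and rating variability summaries, and (when questionnaire
#' columns are present) one-way ANOVA with post hoc t-tests per instrument.
#' When `out_dir` is set, writes ratings, metadata, block means,
#' classification and effects CSVs plus a JSON report with a provenance
#' block (seed, package version, config hash).
#'
#' @param config a [run_config()].
#' @return an object of class `run_report` (list with `proportions`,
#'   `classification`, `effects`, `table1`, `group_summaries`,
#'   `questionnaire_anova`, `provenance`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  tryCatch({
    if (config$mode == "simulate") {
      cohort <- simulate_cohort(config$spec)
      traces <- cohort$traces
      metadata <- cohort$metadata
      paradigm <- config$spec$paradigm
    } else {
      traces <- read_ratings_csv(config$ratings_csv)
      metadata <- if (!is.null(config$metadata_csv))
        read_metadata_csv(config$metadata_csv) else NULL
      paradigm <- config$paradigm
    }
    if (nrow(traces) == 0)
      stop_painmod("empty cohort: nothing to analyse", "painmod_invalid_input")
    timing <- paradigm_timing(paradigm)

    stage <- "preprocess"
    bm <- cohort_block_means(traces, timing)

    stage <- "classify"
    cls <- classify_cohort(bm, config$bootstrap, metadata)

    stage <- "stats"
    effects <- effects_by_group(cls, metadata)
    table1 <- make_table1(effects)
    group_summaries <- group_level_summaries(cls, bm, metadata)
    quest <- questionnaire_anova(cls, metadata)

    report <- structure(list(
      paradigm = paradigm,
      proportions = cls$proportions,
      classification = cls,
      effects = effects,
      table1 = table1,
      group_summaries = group_summaries,
      questionnaire_anova = quest,
      provenance = list(seed = config$bootstrap$seed,
                        n_resamples = config$bootstrap$n_resamples,
                        alpha = config$bootstrap$alpha,
                        package_version = as.character(utils::packageVersion("painmod")),
                        config_hash = config_hash(config))),
      class = "run_report")

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      o <- function(f) file.path(config$out_dir, f)
      write_ratings_csv(traces, o("ratings.csv"))
      if (!is.null(metadata)) write_metadata_csv(metadata, o("metadata.csv"))
      write_block_means_csv(bm, o("block_means.csv"))
      write_classification_csv(cls, o("classification.csv"))
      utils::write.csv(table1, o("effects_table.csv"), row.names = FALSE)
      if (!is.null(group_summaries))
        utils::write.csv(group_summaries, o("group_summaries.csv"), row.names = FALSE)
      jsonlite::write_json(report_as_list(report), o("report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    report
  }, error = function(e) {
    stop_painmod(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)), "painmod_pipeline_error")
  })
}

report_as_list <- function(report) {
  list(paradigm = report$paradigm,
       proportions = report$proportions,
       results = report$classification$results,
       table1 = report$table1,
       group_summaries = report$group_summaries,
       provenance = report$provenance)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> paradigm %s (config %s)\n", x$paradigm,
              x$provenance$config_hash))
  print(x$proportions, row.names = FALSE)
  invisible(x)
}

# Per-subject mean differences on the analysed windows, joined with labels
# and site.
subject_diffs <- function(classification, metadata) {
  df <- classification$results[, c("subject_id", "label", "mean_diff")]
  if (!is.null(metadata) && "site" %in% names(metadata))
    df <- merge(df, metadata[, c("subject_id", "site")], by = "subject_id")
  else df$site <- NA_character_
  df
}

effects_by_group <- function(classification, metadata) {
  df <- subject_diffs(classification, metadata)
  strata <- list(list(group = "main_effect", rows = df))
  for (lab in label_levels) {
    strata <- c(strata, list(list(group = paste0(lab, "s"),
                                  rows = df[df$label == lab, , drop = FALSE])))
  }
  out <- list()
  for (st in strata) {
    sites <- c("all", unique(stats::na.omit(st$rows$site)))
    for (s in sites) {
      rows <- if (s == "all") st$rows else st$rows[st$rows$site == s, , drop = FALSE]
      key <- paste(st$group, s, sep = ".")
      out[[key]] <- if (nrow(rows) >= 2) {
        es <- paired_effect(rows$mean_diff, group = key)
        data.frame(group = st$group, site = s, n = es$n,
                   cohens_d = es$cohens_d, mean_diff = es$mean_diff,
                   sd_diff = es$sd_diff, t_value = es$t_value,
                   p_value = es$p_value)
      } else {
        data.frame(group = st$group, site = s, n = nrow(rows),
                   cohens_d = NA_real_, mean_diff = NA_real_,
                   sd_diff = NA_real_, t_value = NA_real_, p_value = NA_real_)
      }
    }
  }
  do.call(rbind, out)
}

#' Effects table in the classic layout
#'
#' Orders the paired effect summaries as main effect, inhibitors,
#' nonresponders, facilitators, each with all/arm/face rows; columns are
#' Cohen's D, mean and SD of the differences, t and p. Strata absent from
#' the cohort stay as explicit all-NA rows, never silently dropped.
#'
#' @param effects the data.frame from the pipeline's per-group effect pass.
#' @return the reordered data.frame.
#' @export
make_table1 <- function(effects) {
  want_groups <- c("main_effect", "inhibitors", "nonresponders", "facilitators")
  want_sites <- c("all", "arm", "face")
  rows <- list()
  for (g in want_groups) for (s in intersect(want_sites, unique(effects$site))) {
    r <- effects[effects$group == g & effects$site == s, , drop = FALSE]
    if (nrow(r) == 0)
      r <- data.frame(group = g, site = s, n = 0L, cohens_d = NA_real_,
                      mean_diff = NA_real_, sd_diff = NA_real_,
                      t_value = NA_real_, p_value = NA_real_)
    rows[[paste(g, s)]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Percent change / variability / covariate summaries per label, with the
# pairwise normality-gated comparisons.
group_level_summaries <- function(classification, bm, metadata) {
  res <- classification$results
  control_means <- tapply(bm$mean_vas[bm$series == 1L],
                          bm$subject_id[bm$series == 1L], mean)
  test_means <- tapply(bm$mean_vas[bm$series == 2L],
                       bm$subject_id[bm$series == 2L], mean)
  sd1 <- tapply(bm$mean_vas[bm$series == 1L], bm$subject_id[bm$series == 1L],
                stats::sd)
  sd2 <- tapply(bm$mean_vas[bm$series == 2L], bm$subject_id[bm$series == 2L],
                stats::sd)
  ids <- res$subject_id
  ok <- control_means[ids] > 0
  pc <- rep(NA_real_, length(ids))
  pc[ok] <- percent_change(control_means[ids][ok], test_means[ids][ok])
  per_subject <- data.frame(subject_id = ids, label = res$label,
                            pct_change = pc,
                            control_variability = unname(sd1[ids]),
                            test_variability = unname(sd2[ids]))
  rows <- list()
  for (meas in c("pct_change", "control_variability", "test_variability")) {
    for (lab in label_levels) {
      v <- per_subject[[meas]][per_subject$label == lab]
      v <- v[!is.na(v)]
      if (length(v) >= 1) {
        ms <- mean_sem(v)
        rows[[paste(meas, lab)]] <- data.frame(measure = meas, label = lab,
                                               n = ms$n, mean = ms$mean,
                                               sem = ms$sem)
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

questionnaire_anova <- function(classification, metadata) {
  instruments <- c("lotr", "stai_s", "stai_t", "pcs", "bis", "bas")
  if (is.null(metadata) || !any(instruments %in% names(metadata))) return(NULL)
  md <- merge(classification$results[, c("subject_id", "label")], metadata,
              by = "subject_id")
  out <- list()
  for (ins in intersect(instruments, names(metadata))) {
    groups <- split(md[[ins]], factor(md$label, levels = label_levels))
    groups <- Filter(function(g) length(g) >= 2, groups)
    if (length(groups) >= 2 && !anyNA(unlist(groups)))
      out[[ins]] <- anova_with_posthoc(groups, measure = ins)
  }
  if (length(out) == 0) NULL else out
}
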