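# Plain-CSV readers and writers for every pipeline artefact, plus
# JSON/YAML (de)serialisation of the cohort spec. The ratings schema is the
# ingest format for real data as well as the simulator's output.

#' Write / read a long-format ratings table
#'
#' Columns: `subject_id`, `series` (1|2), `time_s`, `vas`.
#'
#' @param traces data.frame of ratings.
#' @param path CSV file path.
#' @return `read_ratings_csv` returns the ratings data.frame.
#' @export
write_ratings_csv <- function(traces, path) {
  utils::write.csv(as_trace(traces)[, c("subject_id", "series", "time_s", "vas")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_trace(df)
  df$series <- as.integer(df$series)
  df
}

#' Write / read the subject metadata table
#'
#' One row per subject: profile fields and questionnaire scores as columns.
#'
#' @param metadata data.frame as produced by [simulate_cohort()].
#' @param path CSV file path.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the block-means table
#'
#' Columns: `subject_id`, `series`, `window_label`, `block` (1-8), `mean_vas`.
#'
#' @param bm block-means data.frame from [cohort_block_means()].
#' @param path CSV file path.
#' @export
write_block_means_csv <- function(bm, path) {
  utils::write.csv(bm, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_means_csv
#' @export
read_block_means_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$series <- as.integer(df$series)
  df$block <- as.integer(df$block)
  df
}

#' Write the per-subject classification table
#' @param classification a `cohort_classification`.
#' @param path CSV file path.
#' @export
write_classification_csv <- function(classification, path) {
  stopifnot(inherits(classification, "cohort_classification"))
  utils::write.csv(classification$results, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / deserialise a cohort spec
#'
#' The spec round-trips through JSON (`.json`) or YAML (`.yaml`/`.yml`),
#' chosen by file extension.
#'
#' @param spec a [cohort_spec()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_cohort_spec` returns a `cohort_spec`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_cohort_spec(cohort_spec(10, seed = 3), f)
#' read_cohort_spec(f)$n_subjects
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  x$class_mix <- as.list(x$class_mix)
  x$delta_mean <- as.list(x$delta_mean)
  x$delta_sd <- as.list(x$delta_sd)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    stop_painmod("spec path must end in .json, .yaml or .yml", "painmod_invalid_input")
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop_painmod("spec path must end in .json, .yaml or .yml", "painmod_invalid_input")
  }
  cohort_spec(n_subjects = x$n_subjects,
              class_mix = unlist(x$class_mix),
              paradigm = x$paradigm,
              delta_mean = unlist(x$delta_mean),
              delta_sd = unlist(x$delta_sd),
              block_noise_mean = x$block_noise_mean,
              block_noise_sd = x$block_noise_sd,
              within_sd_mean = x$within_sd_mean,
              within_sd_sd = x$within_sd_sd,
              baseline_range = unlist(x$baseline_range),
              seed = x$seed)
}
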