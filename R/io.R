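#' Read a cohort from its three CSV inputs
#'
#' Reads and validates the client profiles, long-format daily symptom
#' reports, and medication dose records that make up one cohort.  See
#' [as_client_profiles()], [as_symptom_reports()] and
#' [as_medication_records()] for the schemas and the validation and
#' duplicate-merging rules applied.
#'
#' @param clients_path,reports_path,medications_path paths to CSV files.
#' @return named list with elements `clients`, `reports`, `medications`.
#' @export
read_cohort <- function(clients_path, reports_path, medications_path) {
  list(
    clients = as_client_profiles(read_csv_strict(clients_path), clients_path),
    reports = as_symptom_reports(read_csv_strict(reports_path), reports_path),
    medications = as_medication_records(read_csv_strict(medications_path),
                                        medications_path)
  )
}

read_csv_strict <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("%s, line %d, column %s: malformed value", path,
                 probs$row[1], as.character(probs$col[1])), call. = FALSE)
  }
  df
}

#' Write a cohort back to the three-CSV interchange format
#'
#' Inverse of [read_cohort()]: a written cohort reads back with all fields
#' identical.
#'
#' @param cohort named list with `clients`, `reports`, `medications`.
#' @param dir output directory, created if needed.
#' @return invisibly, the three file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clients.csv", "symptom_reports.csv",
                            "medications.csv"))
  readr::write_csv(cohort$clients, paths[1])
  reports <- cohort$reports
  reports$severity <- NULL # derived, recomputed on read
  readr::write_csv(reports, paths[2])
  readr::write_csv(cohort$medications, paths[3])
  invisible(paths)
}

# Fixed field order of a cohort summary row, mirroring the severity table
# layout of the report.
cohort_summary_columns <- function() {
  c("group_label", "n", "baseline_mean", "baseline_median", "baseline_sd",
    "locf_mean", "locf_median", "locf_sd", "pct_change_of_means",
    "pct_change_of_medians", "effect_size_d", "t_statistic", "p_value",
    "frac_reduction_gt_30", "frac_reduction_gt_50", "frac_symptom_free",
    "frac_worsened")
}

#' Write cohort summary rows to CSV
#'
#' Emits one row per group with columns in the fixed cohort-summary order,
#' keeping the raw unrounded values and appending `*_report` columns in
#' which the percent-change fields are rounded to the nearest integer
#' percent (half away from zero), the convention used in the printed
#' tables.
#'
#' @param summaries tibble of cohort summary rows (see [summarize_group()]),
#'   or a list of such rows.
#' @param path output CSV path.
#' @return invisibly, the tibble written.
#' @export
write_summary <- function(summaries, path) {
  if (inherits(summaries, "data.frame")) {
    df <- tibble::as_tibble(summaries)
  } else {
    df <- dplyr::bind_rows(summaries)
  }
  if (nrow(df) == 0) {
    stop("no summary rows to write", call. = FALSE)
  }
  fixed <- cohort_summary_columns()
  check_columns(df, fixed, "summaries")
  df <- df[c(fixed, setdiff(names(df), fixed))]
  for (col in c("pct_change_of_means", "pct_change_of_medians")) {
    df[[paste0(col, "_report")]] <- round_half_away(df[[col]])
  }
  readr::write_csv(df, path)
  invisible(df)
}

#' Write all analysis tables and a JSON mirror
#'
#' Writes the severity, medication, responder, dropout and selection
#' tables produced by [run_cohort_analysis()] as CSV files plus a single
#' machine-readable JSON mirror of everything.
#'
#' @param results list returned by [run_cohort_analysis()].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_analysis <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  write_summary(results$severity, file.path(dir, "summary_severity.csv"))
  paths <- c(paths, file.path(dir, "summary_severity.csv"))
  w(results$medication, "summary_medication.csv")
  w(results$responders, "summary_responders.csv")
  w(results$dropout$by_month, "dropout.csv")
  w(results$selection, "selection_report.csv")
  w(results$endpoints, "endpoints.csv")
  json_path <- file.path(dir, "analysis.json")
  jsonlite::write_json(
    results[c("severity", "medication", "responders", "dropout",
              "selection", "metadata")],
    json_path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(c(paths, json_path))
}
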