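#' Count distinct in-window reporting days for one client
#'
#' A reporting day is a day `d` with `0 <= d < window_days` on which the
#' client submitted at least one symptom report on any scale.  Days are
#' counted once regardless of how many scales were reported.
#'
#' @param reports symptom report rows for a single client.
#' @param window_days length of the observation window in days (default
#'   180, i.e. six 30-day months).
#' @return integer count of distinct in-window reporting days.
#' @examples
#' r <- tibble::tibble(client_id = "a", day = c(10, 10, 11, 200),
#'                     scale = "bipolar")
#' count_reporting_days(r) # 2
#' @export
count_reporting_days <- function(reports, window_days = 180L) {
  if (nrow(reports) == 0) return(0L)
  days <- unique(reports$day)
  sum(days >= 0 & days < window_days)
}

#' Apply eligibility rules and form the analysis samples
#'
#' A client is admitted when aged 7 to under 18 at monitoring start and
#' has symptom reports on at least `min_days` distinct days of the first
#' `window` days (any scale).  Admitted clients with parent-reported
#' bipolar disorder form the primary sample, split by ADHD comorbidity
#' into two disjoint sub-samples; admitted clients with ADHD but not
#' bipolar form the alternative sample.  Members with no report in
#' months 3-6 (days 60-179) have no endpoint to carry forward; they
#' remain members but are counted under `no_locf_month` in the exclusion
#' tally, and drop out of endpoint analyses in [compute_endpoints()].
#'
#' @param clients client profile tibble.
#' @param reports symptom report tibble.
#' @param min_days minimum distinct reporting days (default 60).
#' @param window eligibility window in days (default 180).
#' @return named list of four sample definitions
#'   (`primary_bipolar`, `bipolar_not_adhd`, `bipolar_and_adhd`,
#'   `adhd_not_bipolar`), each a list with `label`, `member_ids`, and
#'   `excluded_counts` (a named integer vector of exclusion reasons for
#'   the sample's diagnosis-eligible candidates).  The primary sample's
#'   tally additionally records `no_qualifying_dx`: clients with neither
#'   diagnosis, excluded from the analysis altogether.
#' @export
select_samples <- function(clients, reports, min_days = 60L, window = 180L) {
  per_client <- reports |>
    dplyr::group_by(.data$client_id) |>
    dplyr::summarise(
      n_days = count_reporting_days(dplyr::pick(dplyr::everything()),
                                    window_days = window),
      has_locf_month = any(.data$day >= 60 & .data$day < 180),
      .groups = "drop"
    )
  info <- dplyr::left_join(clients, per_client, by = "client_id") |>
    dplyr::mutate(
      n_days = dplyr::coalesce(.data$n_days, 0L),
      has_locf_month = dplyr::coalesce(.data$has_locf_month, FALSE),
      reason = dplyr::case_when(
        .data$age_years < 7 | .data$age_years >= 18 ~ "age",
        .data$n_days < min_days ~ "insufficient_reporting",
        !.data$has_locf_month ~ "no_locf_month", # member; no endpoint
        .default = NA_character_
      )
    )
  eligible <- info$client_id[is.na(info$reason) |
                               info$reason == "no_locf_month"]

  tally <- function(candidates) {
    r <- info$reason[info$client_id %in% candidates]
    counts <- table(factor(r[!is.na(r)],
                           levels = c("age", "insufficient_reporting",
                                      "no_locf_month")))
    out <- as.integer(counts)
    names(out) <- names(counts)
    out
  }

  bip_ids <- info$client_id[info$dx_bipolar]
  adhd_only_ids <- info$client_id[info$dx_adhd & !info$dx_bipolar]
  no_dx <- sum(!info$dx_bipolar & !info$dx_adhd)

  primary <- intersect(bip_ids, eligible)
  adhd_dx <- clients$client_id[clients$dx_adhd]
  sample_def <- function(label, member_ids, excluded_counts = integer(0)) {
    structure(list(label = label, member_ids = member_ids,
                   excluded_counts = excluded_counts),
              class = "sample_definition")
  }
  primary_tally <- c(tally(bip_ids), no_qualifying_dx = no_dx)
  list(
    primary_bipolar = sample_def("primary_bipolar", primary, primary_tally),
    bipolar_not_adhd = sample_def("bipolar_not_adhd",
                                  setdiff(primary, adhd_dx)),
    bipolar_and_adhd = sample_def("bipolar_and_adhd",
                                  intersect(primary, adhd_dx)),
    adhd_not_bipolar = sample_def("adhd_not_bipolar",
                                  intersect(adhd_only_ids, eligible),
                                  tally(adhd_only_ids))
  )
}

#' @export
print.sample_definition <- function(x, ...) {
  cat("<sample_definition> ", x$label, ": n = ", length(x$member_ids), "\n",
      sep = "")
  if (length(x$excluded_counts) > 0) {
    excl <- x$excluded_counts[x$excluded_counts > 0]
    if (length(excl) > 0) {
      cat("  excluded:",
          paste(names(excl), excl, sep = " = ", collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# Long-format exclusion tally across all samples, for selection_report.csv
selection_report <- function(samples) {
  purrr::map_dfr(samples, function(s) {
    tibble::tibble(
      sample = s$label,
      n_members = length(s$member_ids),
      reason = c("included", names(s$excluded_counts)),
      count = c(length(s$member_ids), as.integer(s$excluded_counts))
    )
  })
}
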