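#' Personal maximum dose per medication for one client
#'
#' The Medication Index normalises each medication's dose by the maximum
#' dose that the individual client recorded over the analysis span
#' (pre-treatment baseline period through month 6, i.e. all records with
#' day < 180).  Medications with only zero doses in the span are omitted.
#'
#' @param meds medication record rows for a single client.
#' @param span_end exclusive upper day bound of the analysis span
#'   (default 180).
#' @return named numeric vector: medication -> positive personal maximum.
#' @export
personal_max_doses <- function(meds, span_end = 180L) {
  meds <- meds[meds$day < span_end & meds$dose > 0, , drop = FALSE]
  if (nrow(meds) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(meds$dose, meds$medication, max)
  stats::setNames(as.numeric(out), names(out))
}

# Carried-forward dose of one medication on each requested day: the last
# recorded dose on or before that day persists (0 after a zero-dose
# record, 0 before the first record).
dose_in_effect <- function(record_days, record_doses, days) {
  ord <- order(record_days)
  idx <- findInterval(days, record_days[ord])
  out <- c(0, record_doses[ord])[idx + 1L]
  out
}

#' Medication Index over a window of days
#'
#' For each medication the in-effect dose over the window is the mean of
#' its daily carried-forward dose.  The index is the sum over medications
#' of in-effect dose divided by the client's personal maximum for that
#' medication, so a client taking every medication at personal maximum
#' scores the *count* of medications, and any dose reduction lowers the
#' index by the reduced fraction of that medication's maximum.  The index
#' is therefore unit-free: rescaling one medication's dose records by a
#' positive constant leaves it unchanged.
#'
#' @param meds medication record rows for a single client.
#' @param days integer vector of days making up the window (need not be
#'   contiguous; e.g. the baseline reporting days, or a 30-day month bin).
#' @param personal_max optional precomputed [personal_max_doses()] map.
#' @return non-negative index value.
#' @examples
#' meds <- tibble::tibble(
#'   client_id = "a",
#'   day = c(-7, -7, -7, -7, 150),
#'   medication = c("m1", "m2", "m3", "m4", "m4"),
#'   dose = c(100, 20, 1, 300, 225)
#' )
#' index_at_window(meds, -7:-1) # 4: all four at personal maximum
#' index_at_window(meds, 150:179) # 3.75: one reduced by 25% of maximum
#' @export
index_at_window <- function(meds, days, personal_max = NULL) {
  if (length(days) == 0) stop("empty window", call. = FALSE)
  if (is.null(personal_max)) personal_max <- personal_max_doses(meds)
  if (length(personal_max) == 0) return(0)
  terms <- vapply(names(personal_max), function(m) {
    rec <- meds[meds$medication == m, , drop = FALSE]
    mean(dose_in_effect(rec$day, rec$dose, days)) / personal_max[[m]]
  }, numeric(1))
  sum(terms)
}

#' Baseline and LOCF Medication Index for one client
#'
#' The baseline index is computed over the same days used for the
#' client's severity baseline (internal consistency between the symptom
#' and medication endpoints); the carried-forward index is computed over
#' the full 30-day bin of the client's last reported month.
#'
#' @param meds medication record rows for a single client.
#' @param baseline_days days of the severity baseline window.
#' @param locf_month the client's last reported month (3-6).
#' @return one-row tibble with `baseline_index`, `locf_index`, and a
#'   list-column `personal_max`.
#' @export
medication_index <- function(meds, baseline_days, locf_month) {
  pm <- personal_max_doses(meds)
  locf_days <- seq.int(30L * (locf_month - 1L), 30L * locf_month - 1L)
  tibble::tibble(
    baseline_index = index_at_window(meds, baseline_days, pm),
    locf_index = index_at_window(meds, locf_days, pm),
    personal_max = list(pm)
  )
}

# Days used for the severity baseline of one client/scale: all
# pre-treatment days when there are >= 3, else the earliest 3 reporting
# days (mirrors compute_baseline()).
baseline_window_days <- function(day) {
  day <- sort(unique(day[!is.na(day)]))
  pre <- day[day < 0]
  if (length(pre) >= 3) pre else head(day, 3)
}

#' Medication Index endpoints for every client in a sample
#'
#' @param meds medication record tibble.
#' @param reports symptom report tibble (defines each client's baseline
#'   window days; any scale).
#' @param endpoints endpoint tibble giving each client's `locf_month`.
#' @return tibble with one row per endpoint client: `client_id`,
#'   `baseline_index`, `locf_index`.
#' @export
compute_medication_indices <- function(meds, reports, endpoints) {
  purrr::map_dfr(seq_len(nrow(endpoints)), function(i) {
    id <- endpoints$client_id[i]
    rdays <- reports$day[reports$client_id == id]
    mi <- medication_index(meds[meds$client_id == id, , drop = FALSE],
                           baseline_window_days(rdays),
                           endpoints$locf_month[i])
    tibble::tibble(client_id = id, baseline_index = mi$baseline_index,
                   locf_index = mi$locf_index)
  })
}

#' Cohort medication summary (percent taking and mean indices)
#'
#' Summarises a sample's medication burden the way the medication table
#' of the report does, with three rows: (a) the percent of clients with a
#' positive index at baseline and at LOCF, with their *relative* percent
#' change (drop over baseline percent); (b) the mean index at both
#' endpoints among clients medicated at baseline; (c) the mean index over
#' all clients.  Percent changes are undefined (NA) for a medication-free
#' cohort.
#'
#' @param baseline_index,locf_index paired per-client index vectors.
#' @param group_label label for the output rows.
#' @return three-row tibble: `group_label`, `measure`, `baseline`,
#'   `locf`, `pct_change`.
#' @export
medication_summary <- function(baseline_index, locf_index,
                               group_label = "sample") {
  if (length(baseline_index) == 0) stop("empty sample", call. = FALSE)
  stopifnot(length(baseline_index) == length(locf_index))
  taking_base <- 100 * mean(baseline_index > 0)
  taking_locf <- 100 * mean(locf_index > 0)
  takers <- baseline_index > 0
  mean_takers_base <- if (any(takers)) mean(baseline_index[takers]) else 0
  mean_takers_locf <- if (any(takers)) mean(locf_index[takers]) else 0
  tibble::tibble(
    group_label = group_label,
    measure = c("pct_taking_medication", "mean_index_baseline_takers",
                "mean_index_all_clients"),
    baseline = c(taking_base, mean_takers_base, mean(baseline_index)),
    locf = c(taking_locf, mean_takers_locf, mean(locf_index)),
    pct_change = pct_change(baseline, locf)
  )
}
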