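#' Month bin of a study day
#'
#' The 180-day observation window is tiled by six half-open 30-day bins
#' anchored at treatment start: month `m` covers days
#' `[30 * (m - 1), 30 * m)`.  Days outside `[0, 180)` belong to no month.
#'
#' @param day integer day offsets from treatment start.
#' @return integer month in 1..6, or `NA` outside the window.
#' @examples
#' assign_month(c(0, 59, 60, 179, 180, -1))
#' @export
assign_month <- function(day) {
  out <- 1L + as.integer(floor(day / 30))
  out[day < 0 | day >= 180] <- NA_integer_
  out
}

#' Baseline severity for one client and scale
#'
#' When at least three distinct pre-treatment days (day < 0) carry
#' reports, the baseline is the mean daily severity over *all*
#' pre-treatment days.  Otherwise it falls back to the mean over the
#' earliest three distinct reporting days overall, which may include the
#' first on-treatment days — a conservative choice, since dose titration
#' means little nutrient effect is plausible that early, and any effect
#' there lowers the baseline and so understates improvement.
#'
#' @param day,severity parallel vectors of reporting days (one row per
#'   distinct day; duplicates are merged at ingestion) and severity
#'   totals for a single client and scale.
#' @return baseline severity (numeric scalar).  Fewer than three
#'   reporting days in total raises an endpoint-undefined condition.
#' @export
compute_baseline <- function(day, severity) {
  keep <- !is.na(day) & !is.na(severity)
  day <- day[keep]; severity <- severity[keep]
  if (length(unique(day)) < 3) {
    abort_endpoint_undefined("fewer than 3 reporting days; baseline undefined")
  }
  pre <- day < 0
  if (sum(pre) >= 3) {
    mean(severity[pre])
  } else {
    ord <- order(day)
    mean(severity[ord][1:3])
  }
}

#' Last-observation-carried-forward severity for one client and scale
#'
#' The carried-forward endpoint is the mean severity over all reporting
#' days in the client's last reported month, where months are the 30-day
#' bins of [assign_month()] and only months 3-6 qualify as endpoints.
#'
#' @inheritParams compute_baseline
#' @return list with `locf_severity` (mean over the last reported
#'   qualifying month) and `locf_month` (integer in 3..6).  No report in
#'   months 3-6 raises an endpoint-undefined condition.
#' @export
compute_locf <- function(day, severity) {
  keep <- !is.na(day) & !is.na(severity)
  month <- assign_month(day[keep])
  severity <- severity[keep]
  ok <- !is.na(month) & month >= 3
  if (!any(ok)) {
    abort_endpoint_undefined("no report in months 3-6; endpoint undefined")
  }
  m <- max(month[ok])
  list(locf_severity = mean(severity[!is.na(month) & month == m]),
       locf_month = m)
}

#' Endpoint row from a baseline/LOCF pair
#'
#' Derives the percent change and the classification flags used in the
#' responder tables.  Responder thresholds are strict: a client responds
#' at the 30% (50%) level only when the reduction strictly exceeds 30%
#' (50%) of baseline.  Percent change is undefined (NA) when baseline is
#' 0, and such clients carry no responder flags.
#'
#' @param client_id client identifier.
#' @param scale `"bipolar"` or `"adhd"`.
#' @param baseline_severity,locf_severity endpoint values.
#' @param locf_month month (3-6) the endpoint was carried from.
#' @return one-row tibble with `pct_change`, `responder_30`,
#'   `responder_50`, `symptom_free` and `worsened`.
#' @export
make_endpoints <- function(client_id, scale, baseline_severity, locf_severity,
                           locf_month) {
  pc <- pct_change(baseline_severity, locf_severity)
  defined <- !is.na(pc)
  tibble::tibble(
    client_id = client_id,
    scale = scale,
    baseline_severity = baseline_severity,
    locf_severity = locf_severity,
    locf_month = as.integer(locf_month),
    pct_change = pc,
    responder_30 = defined & pc < -30,
    responder_50 = defined & pc < -50,
    symptom_free = baseline_severity > 0 & locf_severity == 0,
    worsened = locf_severity > baseline_severity
  )
}

#' Severity endpoints for every client on one scale
#'
#' Applies [compute_baseline()] and [compute_locf()] to each client's
#' reports on `scale` and assembles the endpoint table.  Clients whose
#' endpoints are undefined (fewer than three reporting days, or no report
#' in months 3-6 on this scale) are omitted.
#'
#' @param reports symptom report tibble.
#' @param scale `"bipolar"` or `"adhd"`.
#' @param client_ids optional subset of clients to evaluate.
#' @return endpoint tibble, one row per client with defined endpoints.
#' @export
compute_endpoints <- function(reports, scale, client_ids = NULL) {
  r <- reports[reports$scale == scale, , drop = FALSE]
  if (!is.null(client_ids)) r <- r[r$client_id %in% client_ids, , drop = FALSE]
  split_r <- split(r, r$client_id)
  rows <- lapply(names(split_r), function(id) {
    cr <- split_r[[id]]
    tryCatch({
      b <- compute_baseline(cr$day, cr$severity)
      l <- compute_locf(cr$day, cr$severity)
      make_endpoints(id, scale, b, l$locf_severity, l$locf_month)
    }, nutricohort_endpoint_undefined = function(e) NULL)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- make_endpoints(character(0), character(0), numeric(0), numeric(0),
                          integer(0))
  }
  out
}
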