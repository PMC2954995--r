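#' Construct and validate the client profile table
#'
#' A client profile records demographics, the parent-reported diagnosis
#' flags, and the treatment-start anchor used for day numbering (day 0 is
#' the first day of micronutrient use; negative days are pre-treatment).
#'
#' Validation is intentionally shallow here: age and diagnosis rules are
#' eligibility criteria applied by [select_samples()], not ingestion
#' errors, so a 5-year-old row is accepted and later excluded with reason
#' `"age"`.
#'
#' @param df data frame with columns `client_id`, `age_years`, `sex`
#'   (`"male"`/`"female"`), `dx_bipolar`, `dx_adhd`,
#'   `treatment_start_day`.
#' @param source label used in error messages (typically the file path).
#' @return validated tibble of client profiles.
#' @export
as_client_profiles <- function(df, source = "clients") {
  required <- c("client_id", "age_years", "sex", "dx_bipolar", "dx_adhd",
                "treatment_start_day")
  check_columns(df, required, source)
  df <- tibble::as_tibble(df)[required]
  df$client_id <- as.character(df$client_id)
  df$age_years <- check_integerish(df$age_years, source, "age_years")
  df$treatment_start_day <- check_integerish(df$treatment_start_day, source,
                                             "treatment_start_day")
  df$dx_bipolar <- check_logical(df$dx_bipolar, source, "dx_bipolar")
  df$dx_adhd <- check_logical(df$dx_adhd, source, "dx_adhd")
  bad <- which(!df$sex %in% c("male", "female"))
  if (length(bad) > 0) {
    stop_row(source, bad[1], "sex", "must be 'male' or 'female'")
  }
  if (anyDuplicated(df$client_id)) {
    dup <- df$client_id[duplicated(df$client_id)][1]
    stop_row(source, which(df$client_id == dup)[2], "client_id",
             "duplicated client identifier")
  }
  df
}

#' Construct and validate the long-format symptom report table
#'
#' Each row is one client-day's checklist for one scale.  Mood
#' (`"bipolar"`) reports carry 16 item scores; ADHD reports carry 8, of
#' which only the first three (inattention, impulsivity, hyperactivity)
#' enter the severity total.  All item scores must lie in 0..3.
#'
#' Duplicate reports for the same client, day, and scale are merged by
#' item-wise averaging with half-up rounding, after which the severity
#' total is recomputed, so the returned table has one row per
#' client/day/scale.
#'
#' @param df data frame with columns `client_id`, `day`, `scale`, and
#'   `item_1` ... `item_16` (items beyond a scale's length left `NA`).
#' @param source label used in error messages.
#' @return validated tibble with one row per client/day/scale and a
#'   derived integer `severity` column.
#' @export
as_symptom_reports <- function(df, source = "symptom_reports") {
  item_cols <- paste0("item_", 1:16)
  check_columns(df, c("client_id", "day", "scale"), source)
  df <- tibble::as_tibble(df)
  for (col in setdiff(item_cols, names(df))) df[[col]] <- NA_integer_
  df <- df[c("client_id", "day", "scale", item_cols)]
  df$client_id <- as.character(df$client_id)
  df$day <- check_integerish(df$day, source, "day")
  bad <- which(!df$scale %in% scale_names())
  if (length(bad) > 0) {
    stop_row(source, bad[1], "scale",
             paste0("unknown scale label '", df$scale[bad[1]], "'"))
  }
  for (scale in scale_names()) {
    info <- scale_info(scale)
    rows <- which(df$scale == scale)
    for (j in seq_len(info$n_items)) {
      col <- item_cols[j]
      vals <- df[[col]][rows]
      bad <- which(is.na(vals) | !vals %in% c(0, 1, 2, 3))
      if (length(bad) > 0) {
        stop_row(source, rows[bad[1]], col,
                 "item score must be an integer in 0..3")
      }
      df[[col]][rows] <- as.integer(vals)
    }
    # items beyond the scale's length are structurally absent
    for (col in item_cols[-seq_len(info$n_items)]) {
      df[[col]][rows] <- NA_integer_
    }
  }
  df <- merge_duplicate_reports(df)
  df$severity <- severity_from_items(df)
  df
}

# Same-day duplicates for one client/scale: average item-wise, round
# half-up back to integers.
merge_duplicate_reports <- function(df) {
  item_cols <- paste0("item_", 1:16)
  df |>
    dplyr::group_by(.data$client_id, .data$day, .data$scale) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(item_cols),
                    ~ as.integer(round_half_up(mean(.x)))),
      .groups = "drop"
    )
}

#' Severity totals from item scores
#'
#' Applies each scale's scoring rule row-wise: the mood total is the sum
#' of all 16 items (0-48); the ADHD total is the sum of only the first
#' three items (0-9).
#'
#' @param reports symptom report tibble (see [as_symptom_reports()]).
#' @return integer vector of severity totals, one per row.
#' @export
severity_from_items <- function(reports) {
  out <- integer(nrow(reports))
  for (scale in scale_names()) {
    info <- scale_info(scale)
    rows <- reports$scale == scale
    cols <- paste0("item_", info$severity_items)
    out[rows] <- as.integer(rowSums(reports[rows, cols, drop = FALSE]))
  }
  out
}

#' Construct and validate the medication record table
#'
#' Each row is a dated dose statement: from `day` onward the client takes
#' `dose` units of `medication`, until superseded by a later record.  A
#' dose of 0 marks discontinuation.  Dose units are arbitrary and
#' medication-specific; the Medication Index is invariant to per-medication
#' rescaling.
#'
#' @param df data frame with columns `client_id`, `day`, `medication`,
#'   `dose`.
#' @param source label used in error messages.
#' @return validated tibble sorted by client, medication, day.
#' @export
as_medication_records <- function(df, source = "medications") {
  required <- c("client_id", "day", "medication", "dose")
  check_columns(df, required, source)
  df <- tibble::as_tibble(df)[required]
  df$client_id <- as.character(df$client_id)
  df$medication <- as.character(df$medication)
  df$day <- check_integerish(df$day, source, "day")
  df$dose <- as.numeric(df$dose)
  bad <- which(is.na(df$dose) | df$dose < 0)
  if (length(bad) > 0) {
    stop_row(source, bad[1], "dose", "dose must be a non-negative number")
  }
  key <- paste(df$client_id, df$medication, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    stop_row(source, which(duplicated(key))[1], "day",
             "duplicate (client_id, medication, day) record")
  }
  dplyr::arrange(df, .data$client_id, .data$medication, .data$day)
}

check_columns <- function(df, required, source) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(source, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

check_integerish <- function(x, source, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0) {
    stop_row(source, bad[1], col, "must be an integer")
  }
  as.integer(v)
}

check_logical <- function(x, source, col) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- dplyr::case_when(
    v %in% c("true", "t", "1", "yes") ~ TRUE,
    v %in% c("false", "f", "0", "no") ~ FALSE,
    .default = NA
  )
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop_row(source, bad[1], col, "must be a logical (true/false)")
  }
  out
}

stop_row <- function(source, row, col, msg) {
  # data line `row` is physical line row + 1 in a headered CSV
  stop(sprintf("%s, line %d, column '%s': %s", source, row + 1L, col, msg),
       call. = FALSE)
}
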