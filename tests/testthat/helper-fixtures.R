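# Build a validated symptom report table from (day, severity) pairs for
# one client+scale.  Item scores are filled greedily (3s first), which
# realises any severity within the scale's bounds.
make_reports <- function(client_id, days, severities, scale = "bipolar") {
  stopifnot(length(days) == length(severities))
  info <- nutricohort:::scale_info(scale)
  k <- length(info$severity_items)
  rows <- lapply(seq_along(days), function(i) {
    s <- severities[i]
    scored <- pmin(3L, pmax(0L, s - 3L * (seq_len(k) - 1L)))
    items <- rep(NA_integer_, 16)
    items[seq_len(k)] <- scored
    if (info$n_items > k) items[(k + 1):info$n_items] <- 0L
    out <- as.list(items)
    names(out) <- paste0("item_", 1:16)
    c(list(client_id = client_id, day = days[i], scale = scale), out)
  })
  as_symptom_reports(dplyr::bind_rows(rows))
}

# One-call client profile rows
make_clients <- function(ids, dx_bipolar = TRUE, dx_adhd = FALSE,
                         age = 12L, sex = "male") {
  tibble::tibble(client_id = ids, age_years = age, sex = sex,
                 dx_bipolar = dx_bipolar, dx_adhd = dx_adhd,
                 treatment_start_day = 0L)
}

# Endpoint rows straight from numbers, for the statistics modules
make_endpoint_rows <- function(baseline, locf, locf_month = 6L,
                               scale = "bipolar") {
  ids <- sprintf("H%02d", seq_along(baseline))
  dplyr::bind_rows(lapply(seq_along(baseline), function(i) {
    make_endpoints(ids[i], scale, baseline[i], locf[i],
                   rep_len(locf_month, length(baseline))[i])
  }))
}
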