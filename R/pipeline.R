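#' Run the full cohort analysis
#'
#' Applies eligibility selection, computes severity endpoints on both
#' scales, Medication Index endpoints, cohort summaries for the primary
#' sample and its diagnosis sub-samples plus the ADHD-only alternative
#' sample, the subgroup splits (baseline-median, age at 12, sex) for the
#' primary sample, the responder table, and the dropout analysis.
#'
#' @param clients,reports,medications validated input tables (see
#'   [read_cohort()]).
#' @param min_days,window eligibility parameters (see
#'   [select_samples()]).
#' @param out_dir optional directory; when given, all tables plus a JSON
#'   mirror are written via [write_analysis()].
#' @return list with `samples`, `endpoints`, `severity` (cohort-summary
#'   rows per sample and scale), `splits`, `medication`, `responders`,
#'   `dropout`, `selection`, `metadata`.
#' @export
run_cohort_analysis <- function(clients, reports, medications,
                                min_days = 60L, window = 180L,
                                out_dir = NULL) {
  samples <- select_samples(clients, reports, min_days = min_days,
                            window = window)
  ep_bip <- compute_endpoints(reports, "bipolar",
                              samples$primary_bipolar$member_ids)
  adhd_ids <- union(samples$bipolar_and_adhd$member_ids,
                    samples$adhd_not_bipolar$member_ids)
  ep_adhd <- compute_endpoints(reports, "adhd", adhd_ids)
  endpoints <- dplyr::bind_rows(ep_bip, ep_adhd)

  # which endpoint table serves each sample on each scale
  plan <- list(
    list(sample = "primary_bipolar", scale = "bipolar", ep = ep_bip),
    list(sample = "bipolar_not_adhd", scale = "bipolar", ep = ep_bip),
    list(sample = "bipolar_and_adhd", scale = "bipolar", ep = ep_bip),
    list(sample = "bipolar_and_adhd", scale = "adhd", ep = ep_adhd),
    list(sample = "adhd_not_bipolar", scale = "adhd", ep = ep_adhd)
  )
  severity <- purrr::map_dfr(plan, function(p) {
    ep <- p$ep[p$ep$client_id %in% samples[[p$sample]]$member_ids, ,
               drop = FALSE]
    if (nrow(ep) < 2) return(NULL)
    s <- summarize_group(ep, paste(p$sample, p$scale, sep = "."))
    s$scale <- p$scale
    s
  })

  splits <- list(
    bipolar = split_analyses(
      ep_bip[ep_bip$client_id %in% samples$primary_bipolar$member_ids, ],
      clients),
    adhd = split_analyses(
      ep_adhd[ep_adhd$client_id %in% adhd_ids, ], clients)
  )

  medication <- purrr::map_dfr(plan[c(1, 2, 3, 5)], function(p) {
    ep <- p$ep[p$ep$client_id %in% samples[[p$sample]]$member_ids, ,
               drop = FALSE]
    if (nrow(ep) == 0) return(NULL)
    mi <- compute_medication_indices(medications, reports, ep)
    medication_summary(mi$baseline_index, mi$locf_index, p$sample)
  })

  responders <- purrr::map_dfr(plan, function(p) {
    ep <- p$ep[p$ep$client_id %in% samples[[p$sample]]$member_ids, ,
               drop = FALSE]
    defined <- !is.na(ep$pct_change)
    tibble::tibble(
      group_label = p$sample, scale = p$scale, n = nrow(ep),
      frac_reduction_gt_30 = mean(ep$responder_30[defined]),
      frac_reduction_gt_50 = mean(ep$responder_50[defined]),
      n_undefined_pct = sum(!defined)
    )
  })

  dropout <- dropout_analysis(
    ep_bip[ep_bip$client_id %in% samples$primary_bipolar$member_ids, ])

  results <- list(
    samples = samples,
    endpoints = endpoints,
    severity = severity,
    splits = splits,
    medication = medication,
    responders = responders,
    dropout = dropout,
    selection = selection_report(samples),
    metadata = list(min_days = min_days, window = window,
                    multiple_testing_correction = "none")
  )
  if (!is.null(out_dir)) write_analysis(results, out_dir)
  results
}
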