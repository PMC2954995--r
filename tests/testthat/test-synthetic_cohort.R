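test_that("generation is byte-identical under a fixed seed and varies across seeds", {
  a <- generate_cohort(cohort_config(n_clients = 30), seed = 4)
  b <- generate_cohort(cohort_config(n_clients = 30), seed = 4)
  c <- generate_cohort(cohort_config(n_clients = 30), seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$reports, c$reports))
})

test_that("generated records respect scale bounds, score ranges and dose positivity", {
  coh <- generate_cohort(cohort_config(n_clients = 60), seed = 21)
  bip <- coh$reports[coh$reports$scale == "bipolar", ]
  adhd <- coh$reports[coh$reports$scale == "adhd", ]
  expect_true(all(bip$severity >= 0 & bip$severity <= 48))
  expect_true(all(adhd$severity >= 0 & adhd$severity <= 9))
  items <- unlist(coh$reports[paste0("item_", 1:16)])
  expect_true(all(is.na(items) | items %in% 0:3))
  expect_true(all(coh$medications$dose >= 0))
  # severity column always matches recomputation from items
  expect_equal(severity_from_items(coh$reports), coh$reports$severity)
})

test_that("a null-effect noiseless cohort has LOCF exactly equal to baseline", {
  cfg <- cohort_config(n_clients = 25, daily_noise_sd = 0,
                       worsen_frac = 0, mean_reduction = 0)
  coh <- generate_cohort(cfg, seed = 8)
  ep <- compute_endpoints(coh$reports, "bipolar")
  expect_gt(nrow(ep), 0)
  expect_equal(ep$locf_severity, ep$baseline_severity)
  expect_true(all(!ep$worsened))
})

test_that("a deterministic 50% effect is recovered client by client", {
  cfg <- cohort_config(n_clients = 120, daily_noise_sd = 0,
                       worsen_frac = 0, mean_reduction = 0.5,
                       reduction_phi = Inf)
  coh <- generate_cohort(cfg, seed = 12)
  ep <- compute_endpoints(coh$reports, "bipolar")
  j <- dplyr::inner_join(ep, coh$truth, by = "client_id")
  # integer rounding of the daily totals perturbs low-severity clients
  # most; at baseline >= 10 the rounding error is under ~1 point
  j <- j[j$bipolar_baseline >= 10, ]
  expect_gt(nrow(j), 30)
  red <- -j$pct_change
  expect_true(all(abs(red - 50) < 10))
  expect_lt(abs(mean(red) - 50), 2)
})

test_that("full reporting with no early dropout makes everyone eligible with month-6 LOCF", {
  cfg <- cohort_config(n_clients = 40, reporting_rate = 1,
                       dropout = c(m3 = 0, m4 = 0, m5 = 0, m6 = 1))
  coh <- generate_cohort(cfg, seed = 2)
  s <- select_samples(coh$clients, coh$reports)
  n_bip <- sum(coh$clients$dx_bipolar)
  expect_length(s$primary_bipolar$member_ids, n_bip)
  ep <- compute_endpoints(coh$reports, "bipolar",
                          s$primary_bipolar$member_ids)
  expect_equal(nrow(ep), n_bip)
  expect_true(all(ep$locf_month == 6L))
  # under full reporting the endpoint is exactly the month-6 mean
  month6 <- coh$reports[coh$reports$scale == "bipolar" &
                          coh$reports$day >= 150 & coh$reports$day < 180, ]
  m6 <- tapply(month6$severity, month6$client_id, mean)
  expect_equal(ep$locf_severity, as.numeric(m6[ep$client_id]))
})

test_that("the last-reported-month distribution matches the configured categorical", {
  counts <- c(m3 = 0, m4 = 0, m5 = 0, m6 = 0)
  cfg <- cohort_config(n_clients = 200)
  for (seed in 1:5) {
    ep <- compute_endpoints(generate_cohort(cfg, seed = seed)$reports,
                            "bipolar")
    counts <- counts + tabulate(ep$locf_month, 6)[3:6]
  }
  gof <- stats::chisq.test(counts, p = cfg$dropout)
  expect_gt(gof$p.value, 0.001)
})

test_that("infeasible or inconsistent configurations are rejected", {
  expect_error(cohort_config(reporting_rate = 1.2), "config error")
  expect_error(cohort_config(dropout = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(
    cohort_config(baseline_severity = list(bipolar = c(60, 10),
                                           adhd_comorbid = c(5, 2.9),
                                           adhd_only = c(6, 2.5))),
    "scale bounds")
})

test_that("truth comparison reports zero bias on a noiseless cohort and rejects foreign clients", {
  cfg <- cohort_config(n_clients = 40, daily_noise_sd = 0, worsen_frac = 0,
                       mean_reduction = 0)
  coh <- generate_cohort(cfg, seed = 3)
  ep <- compute_endpoints(coh$reports, "bipolar")
  tc <- truth_compare(coh$truth, ep)
  expect_equal(tc$bias[tc$metric == "mean_reduction"], 0)
  expect_equal(tc$bias[tc$metric == "worsened_frac"], 0)
  ep$client_id[1] <- "stranger"
  expect_error(truth_compare(coh$truth, ep), "missing from the truth")
})
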