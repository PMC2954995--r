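test_that("reporting days are counted as distinct in-window days", {
  r <- make_reports("a", 0:59, rep(10, 60))
  expect_equal(count_reporting_days(r), 60L)

  pre_only <- make_reports("a", -5:-1, rep(10, 5))
  expect_equal(count_reporting_days(pre_only), 0L)

  # duplicates on a day and out-of-window days do not count
  mixed <- dplyr::bind_rows(make_reports("a", c(10, 11, 200), rep(8, 3)),
                            make_reports("a", 10, 8, "adhd"))
  expect_equal(count_reporting_days(mixed), 2L)
  expect_equal(count_reporting_days(mixed[0, ]), 0L)
})

test_that("eligibility rules form the four samples from an enumerated cohort", {
  clients <- dplyr::bind_rows(
    make_clients(sprintf("B%d", 1:4), dx_bipolar = TRUE, dx_adhd = FALSE),
    make_clients(sprintf("BA%d", 1:3), dx_bipolar = TRUE, dx_adhd = TRUE),
    make_clients(sprintf("A%d", 1:2), dx_bipolar = FALSE, dx_adhd = TRUE),
    make_clients("U1", dx_bipolar = TRUE, dx_adhd = FALSE)
  )
  full <- function(id) make_reports(id, 0:99, rep(10, 100))
  reports <- dplyr::bind_rows(
    lapply(setdiff(clients$client_id, "U1"), full),
    make_reports("U1", 0:58, rep(10, 59)) # 59 days: one short
  )
  s <- select_samples(clients, reports)
  expect_setequal(s$primary_bipolar$member_ids,
                  c(sprintf("B%d", 1:4), sprintf("BA%d", 1:3)))
  expect_setequal(s$bipolar_not_adhd$member_ids, sprintf("B%d", 1:4))
  expect_setequal(s$bipolar_and_adhd$member_ids, sprintf("BA%d", 1:3))
  expect_setequal(s$adhd_not_bipolar$member_ids, sprintf("A%d", 1:2))
  expect_equal(s$primary_bipolar$excluded_counts[["insufficient_reporting"]],
               1L)
})

test_that("membership boundaries: exactly 60 days in, 59 out, age window half-open", {
  clients <- dplyr::bind_rows(
    make_clients("ok", age = 12L),
    make_clients("young", age = 6L),
    make_clients("seventeen", age = 17L),
    make_clients("eighteen", age = 18L)
  )
  reports <- dplyr::bind_rows(lapply(clients$client_id, function(id) {
    make_reports(id, 0:59, rep(10, 60)) # exactly the minimum
  }))
  s <- select_samples(clients, reports)
  expect_setequal(s$primary_bipolar$member_ids, c("ok", "seventeen"))
  expect_equal(s$primary_bipolar$excluded_counts[["age"]], 2L)
  # pre-treatment reports never count towards the minimum
  r59 <- dplyr::bind_rows(make_reports("ok", 0:58, rep(10, 59)),
                          make_reports("ok", -10:-1, rep(10, 10)))
  s2 <- select_samples(clients[1, ], r59)
  expect_length(s2$primary_bipolar$member_ids, 0)
})

test_that("adding reports never turns a member into a non-member", {
  withr::local_seed(11)
  clients <- make_clients(sprintf("C%d", 1:30))
  for (rep_i in 1:5) {
    reports <- dplyr::bind_rows(lapply(clients$client_id, function(id) {
      days <- sort(sample(0:179, sample(40:90, 1)))
      make_reports(id, days, pmin(48, stats::rpois(length(days), 12)))
    }))
    before <- select_samples(clients, reports)$primary_bipolar$member_ids
    extra_id <- sample(clients$client_id, 1)
    extra <- make_reports(extra_id, setdiff(0:179, reports$day[
      reports$client_id == extra_id])[1:5], rep(5, 5))
    after <- select_samples(clients,
                            dplyr::bind_rows(reports, extra)
                            )$primary_bipolar$member_ids
    expect_true(all(before %in% after))
  }
})

test_that("the diagnosis sub-samples partition the primary sample", {
  for (seed in 1:3) {
    coh <- generate_cohort(cohort_config(n_clients = 80), seed = seed)
    s <- select_samples(coh$clients, coh$reports)
    expect_setequal(c(s$bipolar_not_adhd$member_ids,
                      s$bipolar_and_adhd$member_ids),
                    s$primary_bipolar$member_ids)
    expect_length(intersect(s$bipolar_not_adhd$member_ids,
                            s$bipolar_and_adhd$member_ids), 0)
    expect_length(intersect(s$adhd_not_bipolar$member_ids,
                            s$primary_bipolar$member_ids), 0)
  }
})
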