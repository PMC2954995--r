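test_that("paired test matches closed-form hand computation and t = d * sqrt(n)", {
  # differences 2, 4, 6, 8
  r <- paired_test(c(12, 14, 16, 18), c(10, 10, 10, 10))
  expect_equal(r$mean_diff, 5)
  expect_equal(r$sd_diff, sqrt(20 / 3))
  expect_equal(r$effect_size_d, 5 / sqrt(20 / 3))
  expect_equal(r$t_statistic, r$effect_size_d * sqrt(4))
  expect_equal(r$df, 3L)

  # zero-variance differences are flagged, not infinite
  dg <- paired_test(c(3, 3, 3), c(1, 1, 1))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$t_statistic))
  expect_error(paired_test(1, 1), "n >= 2")
})

test_that("paired and Welch statistics agree with stats::t.test to 1e-10", {
  withr::local_seed(101)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    b <- rnorm(n, 10, 4)
    l <- b - rnorm(n, 2, 3)
    mine <- paired_test(b, l)
    ref <- stats::t.test(b, l, paired = TRUE)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$effect_size_d, mine$t_statistic / sqrt(n),
                 tolerance = 1e-12)

    a <- rnorm(sample(3:40, 1), 0, runif(1, 0.5, 3))
    bb <- rnorm(sample(3:40, 1), runif(1, -1, 1), runif(1, 0.5, 3))
    w <- two_sample_test(a, bb)
    refw <- stats::t.test(a, bb)
    expect_equal(w$t_statistic, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, refw$p.value, tolerance = 1e-10)
  }
})

test_that("Welch test matches the textbook formula on a fixed example", {
  w <- two_sample_test(c(1, 2, 3), c(4, 5, 6))
  # group variances are both 1, so se = sqrt(1/3 + 1/3) and df = 4
  expect_equal(w$t_statistic, -3 / sqrt(2 / 3))
  expect_equal(w$df, 4)
  ident <- two_sample_test(c(5, 5), c(5, 5))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)
  both_const <- two_sample_test(c(5, 5), c(7, 7))
  expect_true(both_const$degenerate)
})

test_that("group summary reproduces a five-client hand computation", {
  ep <- make_endpoint_rows(c(20, 10, 30, 4, 12), c(10, 8, 40, 0, 6))
  s <- summarize_group(ep, "hand")
  expect_equal(s$n, 5)
  expect_equal(s$baseline_mean, 15.2)
  expect_equal(s$baseline_median, 12)
  expect_equal(s$baseline_sd, sqrt(101.2))
  expect_equal(s$locf_mean, 12.8)
  expect_equal(s$locf_median, 8)
  expect_equal(s$pct_change_of_means, 100 * (12.8 - 15.2) / 15.2)
  expect_equal(s$pct_change_of_medians, 100 * (8 - 12) / 12)
  expect_equal(s$effect_size_d, 2.4 / sqrt(56.8))
  expect_equal(s$t_statistic, s$effect_size_d * sqrt(5))
  expect_equal(s$frac_reduction_gt_30, 3 / 5) # -50, -100, -50 qualify
  expect_equal(s$frac_reduction_gt_50, 1 / 5) # strict: -50 does not
  expect_equal(s$frac_symptom_free, 1 / 5)
  expect_equal(s$frac_worsened, 1 / 5)
  expect_equal(s$median_client_pct_change, -50)
  expect_error(summarize_group(ep[1, ], "too_small"), ">= 2")
})

test_that("group summary is permutation-invariant and handles zero baselines", {
  ep <- make_endpoint_rows(c(0, 10, 20, 8), c(0, 5, 8, 12))
  s1 <- summarize_group(ep, "g")
  s2 <- summarize_group(ep[c(3, 1, 4, 2), ], "g")
  expect_equal(s1, s2)
  expect_equal(s1$n_undefined_pct, 1) # the baseline-0 client
  expect_equal(s1$frac_reduction_gt_30, 2 / 3) # over defined clients only
})

test_that("a uniform exact-50% improvement hits the strict threshold boundary", {
  ep <- make_endpoint_rows(c(10, 20, 30, 40), c(5, 10, 15, 20))
  s <- summarize_group(ep, "boundary")
  expect_equal(s$frac_reduction_gt_50, 0)
  expect_equal(s$frac_reduction_gt_30, 1)
})

test_that("responder fraction is non-increasing in the threshold", {
  withr::local_seed(5)
  for (i in 1:10) {
    b <- runif(40, 1, 48)
    l <- pmax(0, b * runif(40, 0.2, 1.4))
    pc <- 100 * (l - b) / b
    fr <- vapply(c(10, 30, 50, 70), function(th) mean(pc < -th), numeric(1))
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("median, age and sex splits follow the documented tie and boundary rules", {
  clients <- dplyr::bind_rows(
    make_clients(sprintf("S%03d", 1:60), age = 11L, sex = "male"),
    make_clients(sprintf("S%03d", 61:120), age = 12L, sex = "female")
  )
  withr::local_seed(9)
  ep <- make_endpoint_rows(sample(seq(1, 48, length.out = 120)),
                           rep(5, 120))
  ep$client_id <- clients$client_id
  sp <- split_analyses(ep, clients)
  expect_equal(sort(sp$median_split$summaries$n), c(60, 60))
  expect_equal(sp$age_split$summaries$group_label,
               c("Age12AndOver", "AgeUnder12"))
  expect_equal(sp$age_split$summaries$n, c(60, 60))
  expect_equal(sort(sp$sex_split$summaries$n), c(60, 60))
  expect_true(all(c("baseline", "locf") %in% sp$median_split$tests$timepoint))

  # identical baselines: the split degenerates to deterministic id order
  ep_tie <- make_endpoint_rows(rep(10, 5), rep(4, 5))
  sp_tie <- split_analyses(ep_tie, make_clients(ep_tie$client_id))
  below <- sp_tie$median_split$summaries
  expect_equal(below$n[below$group_label == "Below"], 3) # odd n: median below
  # age boundary: 12 belongs to the older side
  ep2 <- make_endpoint_rows(c(10, 20, 12, 22), c(5, 5, 5, 5))
  cl2 <- make_clients(ep2$client_id, age = c(11L, 11L, 12L, 12L))
  sp2 <- split_analyses(ep2, cl2)
  expect_equal(sp2$age_split$summaries$n, c(2, 2))
})

test_that("dropout analysis reproduces an enumerated eight-client table", {
  ep <- make_endpoint_rows(
    baseline = c(20, 10, 16, 8, 30, 12, 25, 40),
    locf     = c(10, 8, 4, 6, 15, 3, 5, 10),
    locf_month = c(3, 3, 4, 4, 5, 5, 6, 6)
  )
  d <- dropout_analysis(ep)
  expect_equal(d$by_month$n, c(2, 2, 2, 2))
  # reductions by month: (50,20), (75,25), (50,75), (80,75)
  expect_equal(d$by_month$median_pct_reduction, c(35, 50, 62.5, 77.5))
  m3 <- paired_test(c(20, 10), c(10, 8))
  expect_equal(d$by_month$t_statistic[1], m3$t_statistic)
  cont3 <- two_sample_test(c(20, 10), c(16, 8, 30, 12, 25, 40))
  expect_equal(d$continuation$t_statistic[1], cont3$t_statistic)
  expect_equal(d$continuation$n_stopped, c(2, 2, 2))
  expect_equal(d$continuation$n_continued, c(6, 4, 2))

  # a month with fewer than two clients is flagged unavailable
  d2 <- dropout_analysis(ep[ep$locf_month != 5, ])
  expect_equal(d2$by_month$n[d2$by_month$locf_month == 5], 0)
  expect_true(is.na(d2$by_month$t_statistic[3]))

  # a constant-improvement month recovers its configured median exactly
  ep3 <- make_endpoint_rows(c(10, 20, 30), c(4, 8, 12), locf_month = 6)
  d3 <- dropout_analysis(ep3)
  expect_equal(d3$by_month$median_pct_reduction[4], 60)
})
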