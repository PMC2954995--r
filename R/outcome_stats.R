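#' Paired t-test with Cohen's d for dependent samples
#'
#' Tests the mean of the paired differences `baseline - locf` against
#' zero.  The effect size is Cohen's d for paired data: the mean
#' difference divided by the sample standard deviation (n - 1
#' denominator) of the differences across clients, so that
#' `t = d * sqrt(n)`.
#'
#' @param baseline,locf equal-length paired numeric vectors, n >= 2.
#' @return object of class `paired_test_result`: `n`, `mean_diff`,
#'   `sd_diff`, `t_statistic`, `df`, `p_value` (two-sided),
#'   `effect_size_d`, `degenerate`.  Zero-variance differences are
#'   flagged degenerate with `NA` statistics rather than infinities.
#' @examples
#' paired_test(c(10, 12, 14, 16), c(8, 8, 8, 8))
#' @export
paired_test <- function(baseline, locf) {
  stopifnot(length(baseline) == length(locf))
  d <- baseline - locf
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("paired test requires n >= 2 complete pairs", call. = FALSE)
  s <- sd(d)
  if (s == 0) {
    out <- list(n = n, mean_diff = mean(d), sd_diff = 0, t_statistic = NA_real_,
                df = n - 1L, p_value = NA_real_, effect_size_d = NA_real_,
                degenerate = TRUE)
  } else {
    es <- mean(d) / s
    t <- es * sqrt(n)
    out <- list(n = n, mean_diff = mean(d), sd_diff = s, t_statistic = t,
                df = n - 1L, p_value = 2 * pt(-abs(t), df = n - 1),
                effect_size_d = es, degenerate = FALSE)
  }
  structure(out, class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Paired t-test: n = %d, zero-variance differences (degenerate)\n",
                x$n))
  } else {
    cat(sprintf("Paired t-test: t(%d) = %.3f, p = %.3g, d = %.3f\n",
                x$df, x$t_statistic, x$p_value, x$effect_size_d))
  }
  invisible(x)
}

#' Two-sample t-test for independent groups
#'
#' Defaults to Welch's unequal-variance statistic with the
#' Welch-Satterthwaite degrees of freedom, the robust default when group
#' variances may differ; `var_equal = TRUE` gives the classical pooled
#' test.
#'
#' @param a,b numeric vectors, each with n >= 2.
#' @param var_equal pool the variances (classical Student test)?
#' @return list with `n_a`, `n_b`, `mean_a`, `mean_b`, `t_statistic`,
#'   `df`, `p_value` (two-sided), `degenerate` (both groups
#'   zero-variance).
#' @export
two_sample_test <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("two-sample test requires n >= 2 in each group", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      # identical constants: no evidence of difference
      return(list(n_a = na, n_b = nb, mean_a = mean(a), mean_b = mean(b),
                  t_statistic = 0, df = na + nb - 2, p_value = 1,
                  degenerate = FALSE))
    }
    return(list(n_a = na, n_b = nb, mean_a = mean(a), mean_b = mean(b),
                t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(n_a = na, n_b = nb, mean_a = mean(a), mean_b = mean(b),
       t_statistic = t, df = df, p_value = 2 * pt(-abs(t), df = df),
       degenerate = FALSE)
}

#' Cohort summary row for a group of clients
#'
#' Aggregates a set of endpoint rows into one summary row: baseline and
#' carried-forward means, medians and SDs; percent change of the group
#' means and of the group medians; the paired test and Cohen's d; and
#' responder fractions at strict thresholds.  Clients whose per-client
#' percent change is undefined (baseline 0) are excluded from the
#' responder fractions and counted in `n_undefined_pct`; the
#' `symptom_free` and `worsened` fractions are over all members.  The
#' median of per-client percent changes is also emitted
#' (`median_client_pct_change`), since group-median percent change and
#' median client-level change answer different questions.
#'
#' @param endpoints endpoint tibble rows for the group (one scale).
#' @param group_label label for the row.
#' @return one-row tibble in the fixed cohort-summary column order plus
#'   `median_client_pct_change`, `n_undefined_pct`, `df`.
#' @export
summarize_group <- function(endpoints, group_label) {
  n <- nrow(endpoints)
  if (n < 2) stop("group summary requires >= 2 members", call. = FALSE)
  b <- endpoints$baseline_severity
  l <- endpoints$locf_severity
  tt <- paired_test(b, l)
  defined <- !is.na(endpoints$pct_change)
  tibble::tibble(
    group_label = group_label,
    n = n,
    baseline_mean = mean(b),
    baseline_median = median(b),
    baseline_sd = sd(b),
    locf_mean = mean(l),
    locf_median = median(l),
    locf_sd = sd(l),
    pct_change_of_means = pct_change(mean(b), mean(l)),
    pct_change_of_medians = pct_change(median(b), median(l)),
    effect_size_d = tt$effect_size_d,
    t_statistic = tt$t_statistic,
    p_value = tt$p_value,
    frac_reduction_gt_30 = mean(endpoints$responder_30[defined]),
    frac_reduction_gt_50 = mean(endpoints$responder_50[defined]),
    frac_symptom_free = mean(endpoints$symptom_free),
    frac_worsened = mean(endpoints$worsened),
    median_client_pct_change = median(endpoints$pct_change[defined]),
    n_undefined_pct = sum(!defined),
    df = tt$df
  )
}

#' Subgroup splits with cross-group comparisons
#'
#' Produces the three subgroup analyses reported for the primary sample:
#' (a) a baseline-severity median split — clients ordered by baseline
#' severity (ties broken by client id), bottom half "Below" (the median
#' client falls in "Below" when n is odd), top half "Above"; (b) an age
#' split at 12 or above versus younger than 12 (age at monitoring
#' start); (c) a sex split.  Each side is summarised and the two sides
#' are compared with [two_sample_test()] at baseline and at LOCF.
#'
#' @param endpoints endpoint tibble for one sample and scale.
#' @param clients client profile tibble (for age and sex).
#' @return named list (`median_split`, `age_split`, `sex_split`), each
#'   with `summaries` (two cohort-summary rows, or fewer when a side has
#'   under 2 members) and `tests` (tibble of baseline and LOCF
#'   comparisons; `NA` statistics when a side is too small).
#' @export
split_analyses <- function(endpoints, clients) {
  e <- dplyr::left_join(endpoints,
                        clients[c("client_id", "age_years", "sex")],
                        by = "client_id")
  ord <- order(e$baseline_severity, e$client_id)
  n_below <- ceiling(nrow(e) / 2)
  median_side <- character(nrow(e))
  median_side[ord] <- rep(c("Below", "Above"),
                          c(n_below, nrow(e) - n_below))
  splits <- list(
    median_split = split(e, median_side)[c("Above", "Below")],
    age_split = split(e, ifelse(e$age_years >= 12, "Age12AndOver",
                                "AgeUnder12"))[c("Age12AndOver", "AgeUnder12")],
    sex_split = split(e, e$sex)[c("male", "female")]
  )
  purrr::map(splits, function(sides) {
    sides <- sides[!vapply(sides, is.null, logical(1))]
    summaries <- purrr::imap_dfr(sides, function(side, lab) {
      if (nrow(side) < 2) return(NULL)
      summarize_group(side, lab)
    })
    tests <- if (length(sides) == 2 &&
                 all(vapply(sides, nrow, integer(1)) >= 2)) {
      purrr::map_dfr(
        c(baseline = "baseline_severity", locf = "locf_severity"),
        function(col) {
          ts <- two_sample_test(sides[[1]][[col]], sides[[2]][[col]])
          tibble::tibble(t_statistic = ts$t_statistic, df = ts$df,
                         p_value = ts$p_value)
        }, .id = "timepoint")
    } else {
      tibble::tibble(timepoint = c("baseline", "locf"), t_statistic = NA_real_,
                     df = NA_real_, p_value = NA_real_)
    }
    list(summaries = summaries, tests = tests)
  })
}

#' Dropout analysis by last reported month
#'
#' Groups clients by the month (3-6) their endpoint was carried forward
#' from and reports, per group, the sample size, the median per-client
#' percent reduction, and the paired baseline-vs-LOCF test.  To probe
#' whether early stopping reflects non-response, it also compares the
#' baseline severity of clients stopping at month m against clients
#' continuing past m, for m in 3, 4, 5.
#'
#' @param endpoints endpoint tibble for one sample and scale.
#' @return list with `by_month` (per-month tibble; statistics `NA` where
#'   a group has under 2 members) and `continuation` (stop-vs-continue
#'   baseline comparisons).
#' @export
dropout_analysis <- function(endpoints) {
  by_month <- purrr::map_dfr(3:6, function(m) {
    g <- endpoints[endpoints$locf_month == m, , drop = FALSE]
    reduction <- -g$pct_change
    row <- tibble::tibble(
      locf_month = m, n = nrow(g),
      median_pct_reduction = if (nrow(g) > 0) {
        median(reduction, na.rm = TRUE)
      } else NA_real_,
      t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      effect_size_d = NA_real_
    )
    if (nrow(g) >= 2) {
      tt <- paired_test(g$baseline_severity, g$locf_severity)
      row$t_statistic <- tt$t_statistic
      row$df <- tt$df
      row$p_value <- tt$p_value
      row$effect_size_d <- tt$effect_size_d
    }
    row
  })
  continuation <- purrr::map_dfr(3:5, function(m) {
    stopped <- endpoints$baseline_severity[endpoints$locf_month == m]
    continued <- endpoints$baseline_severity[endpoints$locf_month > m]
    row <- tibble::tibble(stop_month = m, n_stopped = length(stopped),
                          n_continued = length(continued),
                          mean_stopped = NA_real_, mean_continued = NA_real_,
                          t_statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_)
    if (length(stopped) >= 2 && length(continued) >= 2) {
      ts <- two_sample_test(stopped, continued)
      row$mean_stopped <- ts$mean_a
      row$mean_continued <- ts$mean_b
      row$t_statistic <- ts$t_statistic
      row$df <- ts$df
      row$p_value <- ts$p_value
    }
    row
  })
  list(by_month = by_month, continuation = continuation)
}
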