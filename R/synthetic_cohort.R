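#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the statistical structure of the naturalistic
#' cohort the analysis pipeline targets: a mood-scale baseline of mean
#' 17.8 and SD 10.1 on the 0-48 scale, heterogeneous proportional
#' symptom reduction with a worsening minority of 19%, last-reported
#' months 3/4/5/6 in proportions 18/17/16/49%, and 79% of clients
#' medicated at baseline with tapering coupled to realised improvement.
#'
#' @param n_clients number of clients to generate (default 161: the
#'   combined size of a 120-client bipolar cohort and a 41-client
#'   ADHD-only cohort).
#' @param diag_mix probabilities over diagnosis groups
#'   `bipolar_only`, `bipolar_adhd`, `adhd_only` (defaults 91/161,
#'   29/161, 41/161).
#' @param age_range inclusive integer age bounds, sampled uniformly.
#' @param frac_female probability a client is female.
#' @param baseline_severity list of `c(mean, sd)` latent baseline
#'   targets: `bipolar` (0-48 scale), `adhd_comorbid` and `adhd_only`
#'   (0-9 scale).
#' @param mean_reduction mean proportional reduction among improvers
#'   (0-1).
#' @param reduction_phi Beta precision of the improver reduction
#'   distribution; `Inf` gives every improver exactly `mean_reduction`.
#' @param worsen_frac fraction of clients whose symptoms worsen.
#' @param worsen_mean,worsen_sd the worsening minority's proportional
#'   increase is `1 + |N(worsen_mean, worsen_sd)|`.
#' @param trajectory_halflife_days half-life of the exponential approach
#'   from baseline to the post-treatment level (days).
#' @param daily_noise_sd day-to-day severity noise SD for a client at
#'   the reference mood-scale severity (the configured bipolar baseline
#'   mean).  Noise variance scales with the latent level
#'   (`sd = daily_noise_sd * sqrt(latent / reference)`), the
#'   quasi-Poisson behaviour expected of bounded count-like severity
#'   totals: low-severity clients fluctuate less in absolute terms, and
#'   additive homoscedastic noise would be floor-censored for them.
#' @param reporting_rate per-day Bernoulli probability that a client
#'   submits a report.
#' @param dropout probabilities that a client's last reported month is
#'   3, 4, 5 or 6.
#' @param med_p_any probability a bipolar-diagnosed client takes any
#'   psychiatric medication at baseline.
#' @param med_p_any_adhd_only the same probability for ADHD-only
#'   clients, whose medication prevalence is much lower.
#' @param med_count_probs distribution of the medication count (1-4)
#'   among medicated clients.
#' @param taper_intercept,taper_slope logistic link for the monthly
#'   per-medication taper probability,
#'   `plogis(taper_intercept + taper_slope * realised_reduction)`.
#' @param taper_factor multiplicative dose reduction per taper event.
#' @param discontinue_below fraction of the starting dose below which a
#'   tapered medication is recorded as discontinued (dose 0).
#' @param pre_days number of pre-treatment days (reported at
#'   `reporting_rate`) preceding day 0.
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_clients = 161,
                          diag_mix = c(bipolar_only = 91, bipolar_adhd = 29,
                                       adhd_only = 41) / 161,
                          age_range = c(7L, 17L),
                          frac_female = 49 / 120,
                          baseline_severity = list(bipolar = c(17.8, 10.1),
                                                   adhd_comorbid = c(5.0, 2.9),
                                                   adhd_only = c(6.0, 2.5)),
                          mean_reduction = 0.6,
                          reduction_phi = 10,
                          worsen_frac = 0.19,
                          worsen_mean = 0.15,
                          worsen_sd = 0.10,
                          trajectory_halflife_days = 21,
                          daily_noise_sd = 3,
                          reporting_rate = 0.8,
                          dropout = c(m3 = 0.18, m4 = 0.17, m5 = 0.16,
                                      m6 = 0.49),
                          med_p_any = 0.79,
                          med_p_any_adhd_only = 0.41,
                          med_count_probs = c(0.35, 0.35, 0.20, 0.10),
                          taper_intercept = -1,
                          taper_slope = 2.5,
                          taper_factor = 0.5,
                          discontinue_below = 0.25,
                          pre_days = 7L) {
  cfg <- list(n_clients = as.integer(n_clients), diag_mix = diag_mix,
              age_range = as.integer(age_range), frac_female = frac_female,
              baseline_severity = baseline_severity,
              mean_reduction = mean_reduction, reduction_phi = reduction_phi,
              worsen_frac = worsen_frac, worsen_mean = worsen_mean,
              worsen_sd = worsen_sd,
              trajectory_halflife_days = trajectory_halflife_days,
              daily_noise_sd = daily_noise_sd,
              reporting_rate = reporting_rate, dropout = dropout,
              med_p_any = med_p_any,
              med_p_any_adhd_only = med_p_any_adhd_only,
              med_count_probs = med_count_probs,
              taper_intercept = taper_intercept, taper_slope = taper_slope,
              taper_factor = taper_factor,
              discontinue_below = discontinue_below,
              pre_days = as.integer(pre_days))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$diag_mix, cfg$frac_female, cfg$worsen_frac,
             cfg$reporting_rate, cfg$dropout, cfg$med_p_any,
             cfg$med_p_any_adhd_only, cfg$med_count_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (mix in list(cfg$diag_mix, cfg$dropout, cfg$med_count_probs)) {
    if (abs(sum(mix) - 1) > 1e-8) {
      stop("config error: mixture probabilities must sum to 1", call. = FALSE)
    }
  }
  if (cfg$n_clients < 1) stop("config error: n_clients < 1", call. = FALSE)
  if (cfg$mean_reduction < 0 || cfg$mean_reduction > 1) {
    stop("config error: mean_reduction must lie in [0, 1]", call. = FALSE)
  }
  bounds <- c(bipolar = 48, adhd_comorbid = 9, adhd_only = 9)
  for (nm in names(bounds)) {
    m <- cfg$baseline_severity[[nm]][1]
    if (is.null(m) || m < 0 || m > bounds[[nm]]) {
      stop("config error: baseline mean for '", nm,
           "' outside scale bounds", call. = FALSE)
    }
  }
  invisible(cfg)
}

# Latent trajectory multiplier: 1 at treatment start, approaching the
# post-treatment ratio with the configured half-life.
trajectory_factor <- function(day, halflife) {
  f <- numeric(length(day))
  post <- day > 0
  f[!post] <- 1
  f[post] <- if (halflife > 0) 2^(-day[post] / halflife) else 0
  f
}

# Distribute an integer severity total across k items (each 0..3): every
# item gets floor(total/k) and the remainder is spread as +1s over a
# contiguous block at a random rotation.  This is the conditional item
# pattern given the total, so the daily severity tracks the latent
# trajectory exactly; item-level correlation structure is not modelled.
allocate_items <- function(total, k) {
  n <- length(total)
  base <- total %/% k
  rem <- total %% k
  start <- sample.int(k, n, replace = TRUE)
  m <- matrix(base, nrow = n, ncol = k)
  col <- matrix(rep(seq_len(k), each = n), nrow = n)
  m <- m + (((col - start) %% k) < rem)
  storage.mode(m) <- "integer"
  m
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-client latent baselines, a two-component proportional
#' treatment effect (improvers versus a worsening minority), a
#' last-reported month, intermittent daily reporting, integer item-level
#' checklists whose totals track the latent trajectory plus day-to-day
#' noise (clipped to scale bounds), and medication schedules with
#' improvement-coupled monthly tapering.  Clients with a bipolar
#' diagnosis report the 16-item mood scale; clients with an ADHD
#' diagnosis report the 8-item ADHD scale; comorbid clients report both
#' on the same days.  Pre-treatment days `-pre_days..-1` are reported at
#' the same rate as on-treatment days.
#'
#' The same seed and config always reproduce the identical cohort.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @return list with `clients`, `reports`, `medications` (the three
#'   analysis input tables) and `truth` (per-client latent baselines,
#'   assigned proportional change, worsening flag, last reported month,
#'   and baseline medication count).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  withr::with_seed(as.integer(seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_clients
  ids <- sprintf("C%04d", seq_len(n))
  group <- sample(names(cfg$diag_mix), n, replace = TRUE, prob = cfg$diag_mix)
  clients <- tibble::tibble(
    client_id = ids,
    age_years = sample(seq(cfg$age_range[1], cfg$age_range[2]), n,
                       replace = TRUE),
    sex = ifelse(runif(n) < cfg$frac_female, "female", "male"),
    dx_bipolar = group %in% c("bipolar_only", "bipolar_adhd"),
    dx_adhd = group %in% c("bipolar_adhd", "adhd_only"),
    treatment_start_day = 0L
  )

  # latent baselines (clipped away from the bounds' degenerate edges)
  bp <- cfg$baseline_severity
  b_bip <- pmin(pmax(rnorm(n, bp$bipolar[1], bp$bipolar[2]), 1), 48)
  b_adhd <- ifelse(group == "adhd_only",
                   rnorm(n, bp$adhd_only[1], bp$adhd_only[2]),
                   rnorm(n, bp$adhd_comorbid[1], bp$adhd_comorbid[2]))
  b_adhd <- pmin(pmax(b_adhd, 0.5), 9)

  # two-component proportional effect, shared across a client's scales
  worsens <- runif(n) < cfg$worsen_frac
  if (cfg$mean_reduction %in% c(0, 1) || !is.finite(cfg$reduction_phi)) {
    reduction <- rep(cfg$mean_reduction, n)
  } else {
    reduction <- rbeta(n, cfg$mean_reduction * cfg$reduction_phi,
                       (1 - cfg$mean_reduction) * cfg$reduction_phi)
  }
  ratio <- ifelse(worsens,
                  1 + abs(rnorm(n, cfg$worsen_mean, cfg$worsen_sd)),
                  1 - reduction)

  last_month <- sample(3:6, n, replace = TRUE, prob = cfg$dropout)

  # intermittent reporting days over [-pre_days, 30 * last_month)
  span <- cfg$pre_days + 30L * last_month
  client_idx <- rep.int(seq_len(n), span)
  day <- sequence(span) - cfg$pre_days - 1L
  kept <- runif(length(day)) < cfg$reporting_rate
  # guarantee at least one report in the assigned last month
  in_last <- day >= 30L * (last_month[client_idx] - 1L)
  has_last <- tapply(kept & in_last, client_idx, any)
  for (i in which(!has_last)) {
    pool <- which(client_idx == i & in_last)
    kept[pool[sample.int(length(pool), 1)]] <- TRUE
  }
  client_idx <- client_idx[kept]
  day <- day[kept]

  reports <- dplyr::bind_rows(
    build_scale_reports(cfg, "bipolar", clients$dx_bipolar, client_idx, day,
                        ids, b_bip, ratio),
    build_scale_reports(cfg, "adhd", clients$dx_adhd, client_idx, day,
                        ids, b_adhd, ratio)
  ) |>
    dplyr::arrange(.data$client_id, .data$day, .data$scale)
  reports$severity <- severity_from_items(reports)

  p_any <- ifelse(group == "adhd_only", cfg$med_p_any_adhd_only,
                  cfg$med_p_any)
  meds <- generate_medications(cfg, ids, 1 - ratio, p_any)

  truth <- tibble::tibble(
    client_id = ids,
    diag_group = group,
    bipolar_baseline = ifelse(clients$dx_bipolar, b_bip, NA_real_),
    adhd_baseline = ifelse(clients$dx_adhd, b_adhd, NA_real_),
    change_ratio = ratio,
    reduction = 1 - ratio,
    worsened = ratio > 1,
    last_month = last_month,
    n_meds_baseline = attr(meds, "n_meds_baseline")
  )
  attr(meds, "n_meds_baseline") <- NULL
  list(clients = clients, reports = reports, medications = meds,
       truth = truth)
}

build_scale_reports <- function(cfg, scale, has_scale, client_idx, day,
                                ids, latent_baseline, ratio) {
  info <- scale_info(scale)
  keep <- has_scale[client_idx]
  ci <- client_idx[keep]
  d <- day[keep]
  if (length(ci) == 0) return(NULL)
  latent <- latent_baseline[ci] *
    (ratio[ci] + (1 - ratio[ci]) * trajectory_factor(d,
                                                     cfg$trajectory_halflife_days))
  if (cfg$daily_noise_sd > 0) {
    # level-dependent noise: variance proportional to the latent level,
    # anchored so a client at the reference mood severity has SD
    # daily_noise_sd
    ref <- cfg$baseline_severity$bipolar[1]
    sd_day <- cfg$daily_noise_sd * sqrt(pmax(latent, 0) / ref)
    latent <- latent + rnorm(length(latent), 0, sd_day)
  }
  total <- as.integer(round_half_up(pmin(pmax(latent, 0), info$max_severity)))
  k <- length(info$severity_items)
  items <- allocate_items(total, k)
  out <- tibble::tibble(client_id = ids[ci], day = d, scale = scale)
  item_cols <- paste0("item_", 1:16)
  for (j in seq_len(k)) out[[item_cols[j]]] <- items[, j]
  if (info$n_items > k) {
    # remaining recorded-but-unscored items: independent draws around the
    # same per-item intensity as the scored block
    p <- pmin(pmax(total / (3 * k), 0), 1)
    extra <- info$n_items - k
    draws <- matrix(stats::rbinom(length(total) * extra, 3L,
                                  rep(p, extra)),
                    ncol = extra)
    for (j in seq_len(extra)) out[[item_cols[k + j]]] <- as.integer(draws[, j])
  }
  if (info$n_items < 16L) {
    for (j in seq.int(info$n_items + 1L, 16L)) out[[item_cols[j]]] <- NA_integer_
  }
  out
}

generate_medications <- function(cfg, ids, improvement, p_any) {
  n <- length(ids)
  n_meds <- ifelse(runif(n) < p_any,
                   sample(seq_along(cfg$med_count_probs), n, replace = TRUE,
                          prob = cfg$med_count_probs),
                   0L)
  rows <- list()
  if (any(n_meds > 0)) {
    ci <- rep.int(seq_len(n), n_meds)
    med_no <- sequence(n_meds)
    dose0 <- round(runif(length(ci), 10, 500))
    p_taper <- plogis(cfg$taper_intercept + cfg$taper_slope * improvement[ci])
    dose <- dose0
    active <- rep(TRUE, length(ci))
    rows[[1]] <- tibble::tibble(client_id = ids[ci],
                                day = -cfg$pre_days,
                                medication = paste0("med", med_no),
                                dose = dose0)
    for (m in 1:6) {
      taper <- active & (runif(length(ci)) < p_taper)
      if (!any(taper)) next
      dose[taper] <- dose[taper] * cfg$taper_factor
      stop_now <- taper & (dose < cfg$discontinue_below * dose0)
      dose[stop_now] <- 0
      active[stop_now] <- FALSE
      rows[[m + 1]] <- tibble::tibble(client_id = ids[ci][taper],
                                      day = 30L * (m - 1L),
                                      medication = paste0("med", med_no[taper]),
                                      dose = dose[taper])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(client_id = character(0), day = integer(0),
                          medication = character(0), dose = numeric(0))
  }
  out <- dplyr::arrange(out, .data$client_id, .data$medication, .data$day)
  attr(out, "n_meds_baseline") <- n_meds
  out
}

#' Compare pipeline estimates against generator truth
#'
#' Joins the generator's truth record with the pipeline's endpoint table
#' for one scale and reports, per recovered quantity, the configured
#' (realised) truth, the pipeline estimate, the bias, and — for the
#' per-client proportional reduction — the RMSE of the client-level
#' estimates.
#'
#' @param truth truth tibble from [generate_cohort()].
#' @param endpoints endpoint tibble from [compute_endpoints()] for one
#'   scale.
#' @param med_indices optional per-client index tibble from
#'   [compute_medication_indices()]; adds recovery of the
#'   medicated-at-baseline fraction.
#' @return tibble with columns `metric`, `truth`, `estimate`, `bias`,
#'   `rmse`.
#' @export
truth_compare <- function(truth, endpoints, med_indices = NULL) {
  if (!all(endpoints$client_id %in% truth$client_id)) {
    stop("endpoint clients missing from the truth record", call. = FALSE)
  }
  j <- dplyr::inner_join(endpoints, truth, by = "client_id")
  defined <- !is.na(j$pct_change)
  est_red <- -j$pct_change[defined] / 100
  true_red <- j$reduction[defined]
  out <- tibble::tibble(
    metric = c("mean_reduction", "worsened_frac", "responder50_frac"),
    truth = c(mean(true_red), mean(j$worsened.y), mean(j$reduction > 0.5)),
    estimate = c(mean(est_red), mean(j$worsened.x),
                 mean(j$responder_50[defined])),
    rmse = c(sqrt(mean((est_red - true_red)^2)), NA_real_, NA_real_)
  )
  if (!is.null(med_indices)) {
    jm <- dplyr::inner_join(med_indices, truth, by = "client_id")
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "frac_medicated_baseline",
      truth = mean(jm$n_meds_baseline > 0),
      estimate = mean(jm$baseline_index > 0),
      rmse = NA_real_
    ))
  }
  out$bias <- out$estimate - out$truth
  out[c("metric", "truth", "estimate", "bias", "rmse")]
}
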