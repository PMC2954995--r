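---
title: "Methods: endpoint analysis of daily symptom checklists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endpoint analysis of daily symptom checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricohort)
```

## The analysis problem

Naturalistic databases of daily parent-reported symptom checklists differ
from trial data in three ways that drive every design choice in this
package: reporting is voluntary and intermittent; clients stop reporting
at different times (dropout is the norm, not the exception); and there is
no protocol-defined assessment schedule, so endpoints must be constructed
from whatever days were reported. The pipeline therefore works entirely
from three long-format tables — client profiles, daily item-level symptom
reports, and dated medication dose records — and constructs per-client
endpoints rather than fitting trajectories.

Two scales are scored. The mood scale has 16 items rated 0–3 and a
severity total of 0–48. The ADHD scale records 8 items, but only the
first three (inattention, impulsivity, hyperactivity) are specific to
ADHD rather than mood, so its severity total is the sum of those three
(0–9); the remaining items are ingested and stored for auditability but
never scored.

## Eligibility

A client is admitted when aged 7 to under 18 at monitoring start and
reporting on at least 60 distinct days of the first 180. Reporting days
are counted across scales: the minimum-reporting rule exists to ensure
sustained product use and engagement, which a report on either scale
demonstrates equally well (the stricter per-scale reading would only
shrink the samples without changing any endpoint definition). Admitted
bipolar-diagnosed clients form the primary sample, partitioned by ADHD
comorbidity; admitted ADHD-only clients form the alternative sample.
Diagnosis flags are parent-reported and taken at face value.

Members with no report at all in months 3–6 have no endpoint to carry
forward. They remain sample members — the membership rule is exactly the
age and reporting criteria — but are tallied under `no_locf_month` in the
selection report and drop out of every endpoint analysis.

## Endpoints

**Months** are half-open 30-day bins anchored at day 0, so the 180-day
window is exactly six months. No calendar-month definition is available
for data keyed to an arbitrary start day, and uniform bins make the
binning, the eligibility window and the dropout analysis mutually
consistent.

**Baseline** is the mean severity over all pre-treatment reporting days
when at least three exist, otherwise over the earliest three distinct
reporting days. The fallback can include the first on-treatment days;
because doses are titrated up from very low levels, little treatment
effect is plausible there, and any that exists lowers the baseline and
therefore *understates* improvement — the conservative direction.

**LOCF** is the mean severity over all reporting days in the client's
last reported month, months 3–6 only. A single reporting day suffices to
define the bin; imposing a minimum density would silently change the
dropout composition of the cohort. With a report on every day of month 6,
the endpoint is exactly the month-6 mean (a property test asserts this).

**Responder thresholds are strict**: reduction > 30% and > 50% of
baseline. Clients with baseline 0 have undefined percent change; they are
excluded from responder denominators and counted separately
(`n_undefined_pct`) rather than imputed. `symptom_free` requires a
positive baseline and an LOCF of exactly 0; `worsened` is any LOCF above
baseline.

Duplicate same-day reports for one client and scale are merged by
item-wise averaging with half-up rounding; averaging discards the least
information, and rounding keeps item scores on the 0–3 integer grid so
that severity recomputation from items is always exact.

## Medication Index

Dose records carry arbitrary, medication-specific units, so doses are
never compared across medications. For each medication the index takes
the mean daily carried-forward dose over a window (a recorded dose
persists until superseded; 0 after a zero-dose record; 0 before the first
record — prescription semantics) divided by the client's *personal
maximum* recorded dose over the whole analysis span (pre-treatment
through month 6). The index is the sum of these ratios: it equals the
medication count exactly when every medication sits at its personal
maximum, and it is invariant to rescaling any one medication's units.

Two consequences of the span-wide maximum are deliberate and documented:
a medication introduced mid-study is normalised by its own later maximum,
and a mid-study dose increase retroactively lowers the baseline index.
The baseline medication window is the same set of days used for the
severity baseline, keeping the two endpoint families consistent; the LOCF
window is the full 30-day bin of the last reported month. Whether the
index should average within the month or take a point-in-time dose is
underdetermined by its defining example (both agree on constant doses);
the within-month mean was chosen because it is stable under intermittent
dose records.

The cohort summary reports the percent of clients with any medication at
baseline and at LOCF with their *relative* change, and mean indices among
baseline-medicated clients and among all clients. No dose-equivalence
conversion across medications is attempted.

## Statistics

Change from baseline to LOCF uses the paired t statistic, with Cohen's d
for paired data = mean difference / SD of differences, so `t = d√n`.
All SDs use the n−1 denominator. Subgroup comparisons default to Welch's
unequal-variance statistic with Welch–Satterthwaite degrees of freedom
(`var_equal = TRUE` gives the pooled test); Welch is the robust default
when subgroup variances are not known to be equal. Zero-variance inputs
are flagged degenerate rather than returned as infinities. No
multiple-testing correction is applied across the subgroup and dropout
tables — the analysis is descriptive, and the output metadata says so.

Two conventions of "median percent change" exist for such tables: the
percent change of the group medians, and the median of per-client percent
changes. They answer different questions and can differ a lot under
skewed baselines, so both are emitted, as `pct_change_of_medians` and
`median_client_pct_change`.

The **baseline-median split** orders clients by baseline severity with
ties broken by client id; the bottom half is "Below", and with odd n the
median client falls in "Below". The age split puts age 12 in the older
group. Report-table percent columns round half away from zero.

The **dropout analysis** groups clients by last reported month and
reports n, the median per-client percent reduction, and the paired test
per group; it then compares the baseline severity of clients stopping at
month m (m = 3, 4, 5) with those continuing past m, which is the direct
check on whether early stopping marks non-response.

## The synthetic cohort generator

No public data exist for this kind of database, so the generator is a
first-class module: every pipeline stage is exercised against cohorts
whose ground truth is known. It emulates the printed moments of the
target cohort, not a fitted model:

* diagnosis mix 91 : 29 : 41 (bipolar-only : comorbid : ADHD-only) over a
  default 161 clients; ages uniform 7–17; 41% female;
* latent baseline severity N(17.8, 10.1²) clipped to [1, 48] on the mood
  scale, N(5.0, 2.9²) / N(6.0, 2.5²) on the ADHD scale for comorbid /
  ADHD-only clients;
* a two-component proportional effect shared across a client's scales:
  with probability 0.19 the client worsens by a factor
  1 + |N(0.15, 0.1²)|; otherwise the proportional reduction is
  Beta-distributed with mean 0.6 and precision 10 (`reduction_phi = Inf`
  makes the effect deterministic for calibration tests);
* an exponential approach from baseline to the post-treatment level with
  a 21-day half-life — consistent with effects becoming noticeable after
  about two weeks — so that by months 3–6 the trajectory has essentially
  plateaued and LOCF differences across dropout months are small;
* last reported month drawn as 3/4/5/6 with probabilities
  0.18/0.17/0.16/0.49; daily reporting is Bernoulli(0.8), applied also to
  the seven pre-treatment days, with one report forced into the assigned
  last month;
* medication: 79% of bipolar-diagnosed (41% of ADHD-only) clients start
  1–4 medications (mean ≈ 2.05); each month each active medication is
  halved with probability `plogis(-1 + 2.5 · reduction)` — tapering
  coupled to realised improvement, emulating deliberate cross-tapering —
  and is discontinued once below 25% of its starting dose. At the default
  configuration the emergent baseline summary reproduces the target
  pattern (≈79% medicated, mean index ≈ 2.1 among takers).

**Item scores** are generated as the conditional item pattern given the
severity total: every item receives `floor(total/k)` and the remainder is
spread as +1s over a randomly rotated block. The total therefore tracks
the latent trajectory *exactly*, which is what the pipeline consumes;
item-level correlation structure is not modelled, and items are anonymous
indices throughout the package. An unconditional per-item binomial model
was rejected because its per-day variance in the total would break the
exact calibration properties (e.g. a zero-noise null cohort should have
LOCF identically equal to baseline).

**Day-to-day noise** is level-dependent: SD
`daily_noise_sd · sqrt(latent/17.8)`, i.e. variance proportional to the
latent level, anchored so a client at the reference mood severity has the
configured SD (default 3 points). Bounded count-like severity totals
behave this way — a child scoring 2 cannot fluctuate by ±3 daily —
whereas homoscedastic additive noise would be floor-censored for the many
low-severity clients implied by mean 17.8 / SD 10.1, systematically
inflating their observed LOCF and attenuating recovered reductions. No
within-client variance is available to anchor the default; it is a free
parameter.

What passing tests show, and what they do not: the generator reproduces
the cohort's *moments* (baseline distribution, effect mixture, dropout
pattern, medication prevalence and tapering direction), so green tests
demonstrate that the pipeline recovers known structure from data shaped
like the target database. Real checklists also contain item
correlations, autocorrelated mood cycles, reporting gaps correlated with
symptom state, and placebo/expectancy dynamics, none of which are
simulated; no test here speaks to those.

## Numerical and degenerate-input choices

* Half-up rounding for merged item scores; half-away-from-zero for
  report percents; both differ from base R's round-half-to-even on
  purpose.
* Percent change with baseline 0 is `NA` with all responder flags false,
  never `Inf`.
* Zero-variance paired differences or two identical constant groups give
  a degenerate flag; two *different* constant groups also flag rather
  than fabricating an infinite statistic.
* Endpoint preconditions (fewer than three reporting days; no month 3–6
  report) raise a classed condition, and the cohort-level driver converts
  it into omission from the endpoint table.
* Sub-second problem sizes are used throughout the test suite: hand
  fixtures of 3–10 clients for exact arithmetic, generated cohorts of
  25–200 clients for properties, and 20 seeds × 500 clients for the
  parameter-recovery study (a few tens of seconds in total).

## Known limitations

* LOCF is the only imputation implemented; clients retaining residual
  trajectory slope at early dropout bias the recovered mean reduction
  slightly towards zero (about 1–2 percentage points at the default
  half-life, visible in `truth_compare()` output).
* The eligibility window, month length and LOCF month range (3–6) are
  structural constants of the design; `window` is a parameter but the
  month bins are fixed at 30 days.
* Diagnoses, like everything else in the source data, are parent
  reports; the pipeline neither validates nor reweights them.
* The medication taper calibration reproduces the baseline medication
  pattern well; the emergent LOCF medication drop is somewhat shallower
  than the target cohort's printed values, and no attempt is made to fit
  it.
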