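---
title: "Evaluating PDDI fax-alert programmes from pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating PDDI fax-alert programmes from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pharmacy benefit managers (PBMs) adjudicate a large share of outpatient
prescription claims and can therefore spot, within a day of dispensing, that
a patient has been co-prescribed two drugs known to interact (a *potential
drug-drug interaction*, PDDI). One intervention model is retrospective drug
utilization review with prescriber-directed fax alerts: a nightly scan of
claims flags concurrent exposure, and the next morning the prescriber of the
second interacting drug receives an individualized letter with evidence
summaries and management options. Whether such alerts change prescribing is
an empirical question; the natural claims-observable endpoint is a
*successful change* — a fill of a recommended therapeutic alternative within
90 days of the alert — compared against matched patients with the same PDDI
in plans where no alert was sent.

`pddialert` implements that whole evaluation as a tested pipeline:

1. **rulebank** — 18 clinically important PDDI rules (13 evaluable from
   claims, 5 education-only) with drug sets, severities, management
   strategies, and a-priori recommended alternatives;
2. **detection** — nightly-scan-equivalent episode detection on supply-window
   overlap, with alert attribution to the second prescriber;
3. **matching** — 1:1 control selection on age (±2 years), gender, line of
   business, and time period;
4. **outcomes** — 90-day alternative-initiation ascertainment;
5. **stats** — per-cohort and pooled 2×2 comparisons with expected-cell-count
   driven test selection, plus a covariate-adjusted logistic model;
6. **synthetic data** — a claims generator with recorded ground truth, so
   every stage is testable without protected health data.

## Detection model

Each dispensing covers the half-open interval `[fill_date, fill_date +
days_supply)`. A patient is concurrently exposed under a rule when a claim
from the rule's first drug set and one from its second set have overlapping
windows (an optional `grace` parameter, default 0 days, tolerates short
lapses). Overlapping claim pairs are merged into *maximal episodes*; one
episode yields exactly one event — re-scanning an unchanged episode can
never re-alert, while a lapse longer than the grace followed by recurrence
starts a new episode. The event's index date is the fill date of the
chronologically second claim of the episode's initiating pair, and the alert
is addressed to that claim's prescriber. For same-day fills no temporal
order exists; the package deterministically takes the precipitant-side
(second set) drug as "second", an arbitrary but documented convention.
Reversed (voided) claims are excluded everywhere: a reversal means the
prescription was never picked up, and the original programme could not see
it either.

Whether alerts should fire on *prevalent* co-exposure (a refill recreating a
long-standing combination) is a real design fork; the programme alerted on
any detected episode, so the package defaults to that and offers
`incident_only = TRUE` to restrict to first-ever second fills.

## Matching

Controls come from plans where no alerts are sent (patients carry a `plan`
column distinguishing the alert-enabled plan "A" from the control pool "B").
Matching is greedy nearest-age-first within (rule, gender, line of business,
period) strata: rules are processed in descending intervention-event count,
cases within a stratum in patient-id order, and ties among equally aged
candidates go to the lexicographically smallest control patient id. The
procedure is fully deterministic — no RNG — so runs are auditable and
reproducible by sort keys alone. A control patient is consumed by at most
one cohort across the whole study, even with multiple PDDIs; intervention
patients may appear in several cohorts. "Time period" is operationalized as
the calendar month of the index date (configurable to quarter or a ±k-day
window); the source programme left the granularity unstated.

Greedy matching is not guaranteed maximal, but on age-interval compatibility
it tracks the exhaustive optimum closely; the test suite compares it against
a brute-force maximum bipartite matching oracle on small fixtures and never
observed a deficit larger than one pair.

## Outcome definition

`ascertain_changes()` marks an event successful iff a non-reversed claim for
a drug in the rule's alternatives map — keyed by the interacting drugs
actually dispensed, e.g. the statin-azole recommendation depends on which
statin was involved — is filled strictly after the index date and no later
than 90 days after it (day 0 excluded, day 90 included). Initiation alone
suffices: the definition does not require the interacting drugs to stop,
because dose holds and monitoring are invisible in claims. Two stricter
readings are available behind flags, both off by default:
`strict_switch` additionally requires no in-window refill of the interacting
drugs after the change fill, and `incident_alternative` only counts
alternatives absent from the prior 180 days of history. Both arms are
ascertained against their own index dates.

## Inference

Per cohort, the 2×2 table (arm × changed) is tested with the uncorrected
Pearson chi-square unless the minimum expected cell count
(row total × column total / N) is 5 or less, in which case the two-sided
Fisher exact test is used — the conventional "sum of all tables with point
probability not exceeding the observed" definition, computed from
hypergeometric point masses. This selection rule is the one reading of
"small samples (< 5 per group)" under which the package reproduces every
p-value of the source programme's published comparison table from its
printed counts, including the cases that discriminate between candidate
rules (a cohort needing Fisher despite an observed cell above 5, and one
needing the uncorrected chi-square despite an observed cell of 3); that
reproduction is frozen in the test suite. The pooled analysis is a single
unstratified 2×2 over all matched events. Matched-pair dependence is
deliberately ignored, mirroring the source analysis; `pair_results(...,
mcnemar = TRUE)` provides a conditional McNemar analysis as an extension.
No multiplicity adjustment is applied across the 13 cohorts, again
mirroring the source.

The adjusted analysis is a maximum-likelihood logistic regression of
success on the intervention indicator plus specialist status, practitioner
type (reference: physician), acute-medication status of the second drug,
rule severity (reference: moderate), male gender, age group (reference:
65–79), and 12 medication-based comorbidity flags assigned from a 180-day
claims lookback through a shipped drug-class-to-category lookup (a
simplified claims-based risk stratification in the RxRisk spirit; the
exact published mapping is proprietary). Separation and non-convergence
raise explicit diagnostics rather than silent output. The model's fitted
coefficients on real programme data are not reproducible from a
publication — they depend on the underlying claims — so the package's
validation of this stage is parameter recovery on synthetic data.

## The synthetic claims generator

`simulate_population()` emulates the study conditions: an alert-enabled
plan with a large commercial and a small Medicaid line of business (89.7% /
10.3%), ages drawn with stratum weights (0.002, 0.019, 0.282, 0.697) over
(<18, 18–39, 40–64, ≥65), 53.7% female, a prescriber pool that is 87.2%
physicians and 46.6% primary care, per-rule co-prescription rates
proportional to the programme's matched alert mix (normalized to sum to 1
over the 13 evaluable rules), and eligibility extending ≥90 days past the
index for 87.9% of event patients. Per-rule baseline change probabilities
default to the programme's control-arm change rates — a calibration, not
ground truth, since counterfactual no-alert rates are not separately
published. The intervention acts multiplicatively on the change odds:
success is planted with probability `plogis(qlogis(baseline) +
alerted * log(OR))`, with the default OR of 1.18 equal to the pooled crude
odds ratio the programme observed. Education-only rules get a small default
co-prescription rate (0.04 each) so total alerts exceed evaluable alerts,
as in the programme's attrition chain; background ("noise") dispensings at
5 per patient-year, 2% of them reversed, exercise detection filtering and
the comorbidity lookback. The Medicaid stream suppresses
benzodiazepine-azole co-prescriptions, mirroring that plan's alert
exclusion (toggleable).

The control pool is generated as a separate plan three times the size of
the alerted plan. The multiplier reflects that the programme drew controls
from *several* other plans managed by the same PBM and is the smallest
whole multiple at which every evaluable cohort — including the rarest, with
a handful of alerts in six months — acquires matched pairs, as every cohort
did in the programme. A known divergence follows: with so generous a pool
about 90% of eligible synthetic alerts find a match, whereas the programme
matched 43%; whatever frictions produced the unmatched majority there
(period granularity, pool composition) are not identifiable from the
publication, so the generator does not pretend to emulate them.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: NDC-level drug coding and mapping noise,
refill-adherence dynamics (each claim's window is independent; early
refills do not extend exposure), seasonal or secular prescribing trends,
informative eligibility loss, prescriber-level clustering of response, and
any sentinel effect of repeated alerts on future prescribing.

`simulate_matched_outcomes()` is an event-level shortcut for studying the
inference stage alone: it plants outcomes through the same odds-scale
routine as the full generator and attaches effect-free covariates, which
makes estimand-level properties (CI coverage of a planted OR, null
rejection rates) cheap to measure over many replicates without re-running
detection and matching bookkeeping that contributes nothing to those
properties.

## Numerical and edge-case choices

- Dates are day-resolution; all windows are half-open `[start, end)`.
- Ages are completed years at the event's index date; leap-day birthdays
  age on March 1 in common years.
- The Fisher tie tolerance is a relative `1e-7` when comparing point
  probabilities, absorbing floating-point ties exactly as the reference
  implementation in `stats` does; equivalence against exhaustive
  enumeration holds to `<1e-10` over every 2×2 table with N ≤ 60.
- A zero-margin table forces the exact test (the chi-square statistic is
  undefined); an all-zero table is an error, not a p-value.
- Constant covariates are dropped from the regression design; extreme
  coefficients or standard errors trigger a separation warning, and
  all-one-outcome data is an error.
- Problem sizes used by the shipped checks: the study-scale synthetic run
  uses 5,000 alert-plan patients (≈4,700 eligible alerts, matching the
  programme's order of magnitude); operating characteristics use 5,000
  events per arm with 100 (coverage) and 1,000 (null rejection)
  replicates; the oracle sweeps cover all 635,375 contingency tables with
  N ≤ 60 and 100 random claim populations. These sizes give Monte-Carlo
  error well inside the asserted bands while keeping a full run of suite
  plus acceptance script within a few minutes on one core.

## Known limitations

Claims see only what pharmacies submit: monitoring, dose changes,
temporary holds, and patient education — recommended managements for many
of these interactions, and the entirety of the five education-only rules —
are unobservable, which is exactly why only 13 of 18 rules are evaluable.
The matched design controls four confounders; prescriber awareness,
anticoagulation-clinic management, and prior tolerance of the combination
are not controlled and in the source programme plausibly diluted any alert
effect. The package reproduces the analysis machinery and its operating
characteristics; it cannot, and does not claim to, reproduce data-dependent
quantities of the original study such as demographic composition, fitted
regression coefficients, or the attrition counts themselves.
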