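---
title: "Methods: disproportionality screening and time-to-onset modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and time-to-onset modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems (SRS) such as Japan's JADER collect suspected
adverse drug events submitted by clinicians and manufacturers. They have no
exposure denominator, so incidence cannot be estimated; instead, safety
screening asks whether an event is reported *disproportionately* often with
a drug relative to the rest of the database. pvsignal implements that
workflow for databases shipped as four relational tables keyed by a case
number and a version integer:

* `DEMO` — sex, age band, weight band per report;
* `DRUG` — one row per drug entry: name, role (suspected / concomitant /
  interacting), route, administration start and end dates;
* `REAC` — one row per event: MedDRA-style preferred term (PT) code and
  onset date;
* `HIST` — comorbidity terms (carried through but unused by the
  statistics).

## Data model and filtering

**Duplicate resolution.** SRS cases are resubmitted as follow-up arrives;
resubmissions share the case number with a higher version.
`deduplicate_reports()` keeps the highest version per case number. The
identity key and resolution rule are a modelling choice (SRS distributions
do not document a duplicate-detection algorithm); the number of removed
versions is logged so the reduction is auditable, and the operation is
idempotent.

**Exposure eligibility.** A report counts as exposed to a drug only when
the drug appears with role *suspected* and a route in the configured set
for that drug (e.g. intravenous only for glycopeptides, intravenous or
oral for oxazolidinones). Reports where the drug is only concomitant or
interacting are excluded. Routes recorded as *unspecified* are treated as
eligible by default: route fields in real extracts are very frequently
blank, and excluding them would silently drop most of the database. This
is configurable (`include_unspecified_route = FALSE`).

**Dates.** Inputs are ISO `YYYY-MM-DD`, with `YYYY-MM` accepted as a
partial date. Partial dates are retained for disproportionality counting —
which uses no dates — but never enter time-to-onset samples, which require
clearly recorded dates. Drug entries whose end date precedes their start
date are kept with both dates blanked (inconsistent date information).

**Event aggregation.** `build_event_matrix()` counts each term once per
report. At PT level the terms are the report's distinct PT codes. At SMQ
(Standardized MedDRA Query) level a report belongs to an SMQ when at least
one of its PTs maps there with the requested scope; narrow scope is the
default, favouring specificity. MedDRA content is licensed, so the PT→SMQ
dictionary is a user-supplied CSV; the package ships only a fictional
mini-dictionary inside its tests. PTs missing from the dictionary are
excluded from SMQ analyses (with a coverage log) but always retained at PT
level.

## Disproportionality statistics

For a drug–event pair, the case/non-case table is `a` (drug and event),
`b` (drug, no event), `c` (event, no drug), `d` (neither), `N = a+b+c+d`.

* **PRR** `= [a/(a+b)] / [c/(c+d)]`. With `c = 0` the ratio is undefined
  and reported not evaluable, never infinite.
* **Yates-corrected chi-squared.** For a 2×2 table `|O−E|` is the same in
  all four cells, so `Σ max(|O−E|−0.5, 0)² / E` collapses to
  `N(|ad−bc|−N/2)² / [(a+b)(c+d)(a+c)(b+d)]`, zero when `|ad−bc| ≤ N/2`
  (truncation, never a negative correction). The continuity-corrected
  variant is used because it reproduces the reference statistics in both
  the large-count and small-count regimes, where the uncorrected statistic
  visibly diverges (e.g. ~19.2 corrected vs ~25.6 uncorrected for a table
  with `a = 7`).
* **ROR** `= ad/bc` with the Woolf interval
  `exp(ln ROR ∓ z·√(1/a+1/b+1/c+1/d))`. Zero cells make the estimate or
  interval not evaluable; no Haldane–Anscombe 0.5 correction is applied,
  because the signal rule's case-count floor makes corrected estimates
  irrelevant to decisions.
* **IC / IC025.** The shrinkage observed-to-expected information
  component: `E = (a+b)(a+c)/N`, `IC = log2((a+0.5)/(E+0.5))`, and `IC025`
  from the exact 2.5% Gamma(`a+0.5`, scale 1) quantile in the numerator.
  The gamma-quantile formulation was chosen over the common
  `IC − 3.3/√a` approximation because it matches reference values more
  closely at large counts; at small counts different published
  formulations diverge by up to ~0.2 bits, so IC025 is treated as a
  descriptive sensitivity measure here, not a primary decision statistic.

**Log-scale p-values.** With `N` near 10⁶, chi-squared statistics in the
thousands arise routinely and their p-values underflow double precision
(`exp(-2500)`). All p-value handling is therefore on the natural-log
scale: `log_p_from_chi2()` uses the log-scale survival function, and
`bh_adjust_log()` performs the Benjamini–Hochberg step-up adjustment
entirely in log space (`log p_(i) + log(m/i)`, running minimum from the
top, capped at 0). It agrees with `p.adjust(..., "BH")` to 1e-12 wherever
the latter does not underflow.

**BH family.** The adjustment family is per drug and per level: `m` is the
number of terms tested for that drug (those with `a ≥ 1`). This matches
the screening design — each drug's profile over ~110 narrow SMQs is one
family of hypotheses — and is consistent with the magnitudes of published
log-adjusted p-values, which sit `ln(m/i)` above the raw log p for
within-drug rank `i`. A pooled family across drugs is available via
`fdr_family = "global"`. Ties in log p are broken by term id so sorted
order, and hence output, is reproducible.

**Signal rule.** A pair is flagged when all four conditions hold:
PRR ≥ 2, chi-squared ≥ 4, `a` ≥ 3, and BH-adjusted p < 0.05 (compared in
log space). The four booleans are exported per pair so decisions are
auditable. Volcano coordinates are `x = log2(PRR)`, `y` = chi-squared,
point size the within-drug reporting ratio `a/(a+b)`.

## Time-to-onset model

`extract_tto()` computes days from the start of the suspected drug's
administration to event onset, with same-day onset counted as day 1 (the
Weibull needs positive support, and whole-day resolution cannot
distinguish within-day ordering). Eligibility: complete start and onset
dates; onset not before start; onset at most 14 days after a complete end
date (configurable window); a missing end date means treatment is ongoing,
so onset ≥ start suffices. With several suspected entries of the drug in
one report the earliest start is used, and with several qualifying events
the earliest onset — one value per report, preventing double counting.
The fixed 14-day post-cessation window is a deliberate simplification;
event types with longer latencies are differentially censored by it.

`fit_weibull_tto()` fits the two-parameter Weibull by maximum likelihood
(via fitdistrplus), with Wald 95% confidence intervals from the observed
information on the untransformed scale — which is why an interval can dip
below 1 while the point estimate is above it. At least 20 cases are
required; smaller or zero-variance samples are reported not evaluable,
with the empirical median and IQR (linear-interpolation quantiles) still
given.

The hazard-shape label follows the shape-parameter interval:
*wear-out* when the whole 95% CI for β lies above 1 (risk increasing with
treatment duration), *early* when it lies below 1, *random* otherwise.
The interval rule, rather than a point-estimate rule, is used because it
is the only operationalisation of "β ≈ 1" consistent with the reference
classifications this package validates against.

**Goodness of fit.** The Anderson–Darling statistic is computed against
the fitted Weibull CDF and its p-value from the fully-specified-null
distribution (Marsaglia & Marsaglia's evaluation, implemented in the
package because no installed dependency exposes this test). Because the
parameters are estimated from the same sample, this plug-in usage is
*conservative* as a formal test — simulation in the test suite shows a
1%-level rejection rate below nominal under the null — so p-values should
be read as a descriptive adequacy measure, which is how such values are
conventionally reported in this setting.

## Synthetic data generator

`generate_srs()` draws databases in the exact input schema with known
ground truth, which is what the package's end-to-end validation runs on:

* drugs are included independently per report with configured marginal
  probabilities; roles and routes are drawn from configured distributions
  (shared across drugs — per-drug distributions would add parameters
  without exercising any additional code path);
* a term occurs with probability `baseline × Π λ` over the report's
  *suspected* exposures to drugs with a planted signal on the term, capped
  at 1. Defining exposure as suspected presence makes the planted
  mechanism coincide with the screen's eligibility rule, so
  `expected_prr()` — exact enumeration over the joint exposure states of
  all signal drugs of a term — is the estimand the screen targets when all
  routes are allowed;
* onsets are the generating drug's start plus a Weibull day count
  (planted per pair, or the default α = 10, β = 1 constant-hazard
  latency), rounded up to whole days; start dates are uniform over a
  window and durations geometric (mean 10 days), so the post-cessation
  window rule is exercised;
* a configured fraction of case numbers gains a duplicate version, and a
  fraction of dates is blanked or truncated to year-month (default 5% and
  10%, typical of the messiness the loader must absorb);
* one RNG stream per generation block is derived from the single seed, so
  adding a block does not perturb earlier draws, and output is bitwise
  reproducible.

Deliberately **not** modelled: polypharmacy and confounding by indication,
reporting-rate time trends (Weber effect), correlated events, or real
marginal frequencies. Passing the synthetic round-trip therefore shows
the estimators and rules are implemented correctly under the stated
model — not that real SRS signals are unconfounded.

## Validation and problem sizes

The test suite validates, among others:

* all published SMQ-level PRR / corrected chi-squared / ROR values
  reproduce to their printed precision from their printed counts (45
  rows), and every published shape-interval classification reproduces
  (27 groups, 17 of them wear-out);
* β-CI coverage near 95% (±3%) for planted (α, β) ∈ {(10, 0.7), (10, 1.0),
  (15, 1.8)} at n = 200 over 500 replicates each;
* a null database (all λ = 1, 1000 terms, 50 000 reports, 10 seeds) keeps
  the flagged fraction within the FDR bound — in practice near zero,
  because the PRR/chi-squared/count conditions bind far before the BH
  condition;
* planted λ = 8 pairs at baseline 0.01 in 50 000-report databases are
  recovered in ≥ 95% of 20 seeded runs;
* closed forms agree with brute-force oracles (four-cell chi-squared
  summation, set-algebra 2×2 construction, set-image SMQ aggregation).

These sizes were chosen as the smallest at which the stochastic properties
are stable enough to assert tightly; the deterministic checks are exact.

## Interface notes

The package is function-first: a structured YAML run configuration
(`read_run_config()`) drives `run_signal_screen()` and
`run_tto_analysis()`, which export per-drug CSV tables whose every
statistic is recomputable from the 2×2 counts in the same row, volcano and
box-plot coordinate CSVs, and optional PNG figures rendered from those
coordinate files (never from internal state). Real JADER distributions are
Shift-JIS encoded with Japanese headers; converting them to this package's
documented UTF-8 schema is a mechanical renaming/transcoding step left to
the user, and no network access is performed.
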