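---
title: "Methods: disproportionality and time-to-onset analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsignal)
```

## The data model

A spontaneous reporting system in the JADER schema consists of four
relational tables keyed by an opaque `report_id`: `demo` (sex, age in
10-year bands, reporting year), `drug` (drug name, role code, start
date), `reac` (MedDRA preferred-term code, onset date) and `hist`
(primary illness; loaded and round-tripped but not analysed). Role
codes distinguish *suspected*, *interacting* and *concomitant* drugs;
all analyses here use suspected-role records only, since the role code
is the reporter's causal attribution. The schema carries no
case-identification key, so no deduplication or record linkage is
attempted — duplicate submissions remain distinct reports, as they do
in practice.

The event of interest is a set of PT codes (default: the three SJS/TEN
terms 10042033, 10030081, 10044223). PT codes are opaque strings; the
package deliberately knows nothing of the MedDRA hierarchy, which is
licensed. A report is a *case* if any of its reaction records matches
the set; case status is therefore monotone in the PT set, a property
the tests exercise.

Age bands are merged into five analysable strata (≤19, 20–39, 40–59,
60–79, ≥80 years). Bands "0s" and "10s" both map to the youngest
stratum and "90s"/"100s" to the oldest, since the strata are defined by
their decade boundaries rather than an enumerated band list. Reports
with unknown sex or unparsable age band are removed by the
complete-case filter (counted and logged); reports whose only drugs are
interacting or concomitant remain in denominators but contribute to no
drug's exposed cell — they are genuine reports, merely unexposed for
every analysed drug.

Drug-name matching is exact after Unicode NFKC normalization and
case-folding. Brand/generic synonymy differs by country and source, so
synonym mapping is left to a user-supplied table applied before
loading; building a partial one in would hide mismatches rather than
fix them.

## Crude reporting odds ratio

For a drug (or drug group — a group's exposed margin is the union of
its members' reports, each report counted once) the 2×2 table counts
*reports*, not drug records. The ROR is ad/(bc) with the Woolf
(log-normal) 95% interval; `z` is fixed at 1.959964 and the level is
configurable. A signal requires estimate and lower limit both ≥ 1 — the
boundary value counts, so an interval whose lower limit is exactly 1 is
still a signal, while for the hazard test below an interval touching 1
does *not* exclude it. If any cell is zero the Haldane–Anscombe
correction adds 0.5 to all four cells and flags the result; this keeps
the estimator finite at the cost of a small shrinkage toward 1, and is
the standard pharmacovigilance convention. A margin that is entirely
zero (no exposed reports, or no cases at all) leaves the ROR undefined
and raises an error rather than returning a corrected artifact.

## The adjustment model

Case status is regressed on reporting year (one linear term, offset by
the first configured year so the intercept is well-conditioned), a
female indicator, and four age-stratum indicators with 40–59 years as
reference. The single linear year term is a deliberate choice: the
adjusted analysis reports one "reporting year" coefficient per block,
and a per-year factor coding would change the estimand. Estimation is
Newton–Raphson (equivalently iteratively reweighted least squares) with
step-halving, so the log-likelihood is non-decreasing across
iterations; convergence requires the score sup-norm or the relative
log-likelihood change to fall below 1e-8, within 100 iterations.
Coefficient divergence (|β| > 30 on these standardized codings) is
reported as perfect separation rather than silently returning an
enormous estimate. The covariance is the inverse observed information
at the optimum; adjusted RORs are exp(β) with Wald intervals
exp(β ± 1.96·SE). Each term is also tested by a likelihood-ratio test
against the model without that column, with the statistic referred to
χ²(1); significance is declared at p ≤ 0.05 (inclusive, "0.05 or
less"). Constant design columns — an unpopulated stratum, a single-sex
subset — are dropped with a warning before fitting, as a
perfect-separation guard.

Subset analysis refits the same model inside the reports exposed to one
drug or drug class: the subset approximates a population sharing a
therapeutic context, which mitigates confounding by indication. Blocks
whose outcome does not vary, or whose fit fails, are skipped with a
warning rather than aborting the whole-data analysis.

On a saturated 2×2 problem the model reproduces the sample odds ratio
exactly and the LRT statistic equals the G-statistic; both identities
are tested against independent oracles (closed form, `stats::glm`, a
direct G-statistic computation).

## Time-to-onset and the Weibull shape parameter test

For each (report, drug) pair with the drug suspected, the report a
case, and both dates at full day precision, the duration is the
earliest qualifying onset date minus the earliest start date of that
drug in the report, in whole days. Month- or year-precision dates are
excluded and counted, as are negative durations (onset before first
prescription — usually a data-entry artifact). When a report has
several qualifying reaction records, the earliest is used: the first
onset is the clinically meaningful latency, and later records commonly
re-describe the same episode.

Descriptive quartiles use the (n+1)p linear-interpolation convention
(R's `type = 6`): on {1, 2, 3, 8, 20} it gives Q1 = 1.5, median = 3,
Q3 = 14. Quartiles are descriptive only; the convention matches the
common statistical packages used for this kind of analysis.

The two-parameter Weibull density
f(t) = (β/α)(t/α)^(β−1) exp(−(t/α)^β) is fit by maximum likelihood
with no censoring — a spontaneous report exists only because the event
occurred, so there is no at-risk time to censor. The scale is profiled
out in closed form, α(β) = (mean tᵝ)^(1/β), and the shape solves the
profile score equation by safeguarded Newton iteration (a bracketing
interval with bisection fallback; tolerance 1e-10 on the score; start
value 1.2825/sd(log t), the moment estimator from
var(log T) = π²/6β²). Durations are pre-scaled to geometric mean 1 for
conditioning and the scale is restored afterwards, which is what makes
the fit exactly scale-equivariant (a tested property). Confidence
intervals are Wald on (log α, log β) using the observed information
(central finite differences, step 1e-4 on the log scale),
exponentiated; profile-likelihood intervals are available via
`ci_method = "profile"` for sensitivity.

Zero durations — an onset on the day of first prescription, which the
data genuinely contain — are shifted to 0.5 day before fitting because
the log-density is undefined at 0 (β < 1); descriptive statistics keep
the raw zeros. The half-day convention treats a same-day onset as
mid-day on average and is configurable (`zero_shift`).

Fits are refused below n = 10 (configurable) and warned about below
n = 100, where shape intervals are too wide to classify hazards
reliably. The hazard classification is: INCREASING if β > 1 with the
95% CI excluding 1; DECREASING if β < 1 with the CI excluding 1;
CONSTANT_COMPATIBLE otherwise — including when a CI bound equals 1
exactly, since touching a value does not exclude it.

## The synthetic-data generator

`generate_database()` emulates the study conditions of a national-scale
database: per report it draws sex, a decade age band, a reporting year
(uniform over the configured range); independent per-drug suspected
exposures; case status from the logistic model above; and, for each
suspected catalogue drug on a case report, an onset date equal to that
drug's start date plus a rounded Weibull latency. Drug–event
association is induced by multiplying the case *odds* by each exposed
drug's `enrichment_or` rather than by adding drug terms to the logistic
model; with a rare outcome this makes the marginal drug–event odds
ratio approximately the configured multiplier while leaving the
covariate coefficients interpretable, so crude-ROR recovery and
adjusted-coefficient recovery can be tested independently. Every report
also carries one background suspected drug (every real report names at
least one suspected drug), a 30% chance of a concomitant-role record
(exercising the role filter), and non-case reports get a background PT
code. Missingness is completely at random, applied after generation, to
sex, age band, start dates and onset dates separately.

`default_sim_config()` fixes the study conditions: sex and age-band
mixes and a 1.86% marginal case fraction matching a national database's
published margins (the intercept is solved numerically against the
exact covariate/exposure mixture via `expected_case_fraction()`); five
catalogue drugs whose exposure probabilities (0.75%, 1.33%, 0.54%,
1.28%, 0.67%) and enrichment odds ratios (14.86, 7.12, 19.89, 5.73,
11.45) reproduce the published per-drug report and case counts; per-drug
Weibull latencies of (45.66, 0.62), (9.44, 0.64), (6.17, 0.74),
(31.20, 1.02), (46.66, 0.71) (scale in days, shape dimensionless);
stratum coefficients 0.284, 0.579, −0.349, −0.327, year −0.025, female
0.104; missingness of 1.7% (sex) and 5% (age), so ≈6.6% of reports fail
the complete-case filter, and 5%/4.7% for start/onset dates, so ≈9% of
drug–event combinations lack complete dates. These were chosen once
from the published margins and are not tuning knobs.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: duplicate submissions,
informative missingness (real incompleteness correlates with report
severity and source), secular trends in drug usage and coding practice,
correlated co-prescription (exposures are independent here),
indication-driven confounding beyond the covariates in the model, and
reporting-delay truncation of recent onsets. Recovery tests demonstrate
the estimators are correct under the stated model, not that the model
captures every bias of a passive surveillance system.

## Problem sizes and runtime choices

The test suite runs recovery checks at 20,000–50,000 reports (10
replicates at 50,000 for adjusted-ROR coverage), calibration at 1,000
null contingency tables and 500 likelihood-ratio replicates, and
Weibull recovery at the published per-drug sample sizes (340, 281, 270)
with 200 replicates for bias; the acceptance script uses a single
200,000-report database. These sizes keep full runs to a few minutes
while leaving Monte-Carlo error well below the tolerances being
asserted.

## Known limitations

* Crude RORs from a passive system indicate reporting
  disproportionality, not incidence or absolute risk; adjusted RORs
  control only the modelled covariates.
* The year term is linear on the log-odds scale; strong non-monotone
  secular trends would be mis-modelled (use the year-stratified counts
  table to inspect).
* The Weibull fit assumes a single homogeneous latency population per
  drug; mixtures (e.g. immediate re-challenge cases plus first
  exposures) bias the shape toward values below 1.
* Wald intervals on log-parameters are asymptotic; below n ≈ 100 use
  `ci_method = "profile"` and read the classification cautiously — the
  fit warns accordingly.
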