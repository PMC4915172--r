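# srsignal

Signal detection and time-to-onset analysis for spontaneous adverse
event reporting databases in the four-table JADER schema (`demo`,
`drug`, `reac`, `hist`).

Spontaneous reporting systems are the primary tool for detecting rare,
severe drug reactions — such as Stevens-Johnson syndrome and toxic
epidermal necrolysis (SJS/TEN) — after marketing. Because these
databases have no denominator population, association is measured by
*disproportionality*: for a 2×2 cross-classification of reports by drug
exposure and event,

```
                 event   other events
  drug             a          b
  all other drugs  c          d
```

the reporting odds ratio is ROR = ad / (bc), with the Woolf interval
exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)); a *signal* requires both
the estimate and the lower 95% limit to be ≥ 1. Confounding by age,
sex and reporting period is controlled with a logistic model

```
log(odds of case) = β0 + β1·Y + β2·G + β3·A
```

where Y is the reporting year, G a female indicator and A four
indicators for the age strata ≤19, 20–39, 60–79 and ≥80 years (40–59 as
reference); exp(β) is the *adjusted ROR*, tested per term by a 1-df
likelihood-ratio test, on the whole database or within a drug-exposed
subset. The onset pattern of a reaction is characterised by fitting a
two-parameter Weibull distribution to the days from first prescription
to onset: a shape β < 1 whose 95% CI excludes 1 indicates a
falling hazard (early-failure pattern), β ≈ 1 a constant one (the
Weibull shape parameter test).

The package implements the whole workflow — ingestion and complete-case
filtering, crude and adjusted RORs, the Weibull time-to-onset analysis —
plus a synthetic JADER-schema database generator with known ground
truth, so every stage is testable end to end without access to the real
(downloadable but evolving) database.

## Worked example

```r
library(srsignal)

cfg <- default_sim_config(n_reports = 20000, rng_seed = 42)
gen <- generate_database(cfg)          # four-table database + ground truth
ds  <- build_analysis_dataset(gen$db)  # complete-case, per-report rows
#> build_analysis_dataset: 18649 of 20000 reports retained
#> (1351 removed for missing sex/age)

crude_ror(build_contingency(ds, "allopurinol"))
#> ROR 12.89 (95% CI 8.52-19.49) *signal*

adj <- run_adjusted_analysis(ds, list(loxoprofen = "loxoprofen"))
adj[adj$block == "total", c("term", "beta", "ror", "ci_low", "ci_high", "lrt_p")]
#>        term     beta   ror ci_low ci_high   lrt_p
#> 1      year -0.01555 0.985  0.956    1.01 0.29974
#> 2    female  0.06620 1.068  0.872    1.31 0.52231
#> 3   ageLE19 -0.00431 0.996  0.658    1.51 0.98373
#> 4 ageY20_39  0.46388 1.590  1.148    2.20 0.00598
#> 5 ageY60_79 -0.21008 0.811  0.621    1.06 0.12520
#> 6   ageGE80 -0.07068 0.932  0.649    1.34 0.70019

fit_weibull(compute_durations(gen$db, "loxoprofen"))
#> Weibull fit (n = 26): scale 6.22 (3.85-10.03), shape 0.85 (0.64-1.14)
#> [CONSTANT_COMPATIBLE]
```

The crude ROR of 12.89 recovers the generator's allopurinol enrichment
(odds multiplier 14.86) within sampling error at this scale; the
whole-data block shows the 20–39-year stratum elevated (adjusted ROR
1.59, LRT p = 0.006) as generated (true exp(0.579) = 1.78); and the
loxoprofen onset latencies, generated from a Weibull with scale 9.44
days and shape 0.64, give a shape estimate of 0.85 whose interval at
n = 26 still includes 1 — the small-sample caution the warning points
at.

`run_pipeline()` orchestrates all stages from a YAML or list config
(file input or inline simulation) and writes `table1_counts.csv`,
`table2_adjusted_ror.csv`, `table3_tto.csv`, per-drug onset histograms
and a `manifest.json` with filter-step accounting. A thin command-line
wrapper lives at `inst/cli/srsignal-pipeline.R` (subcommands `simulate`
and `report`).

## Scope

PT codes are opaque strings (no MedDRA hierarchy), there is no record
deduplication (the schema has no case-identification key), and no
censoring model is fit (spontaneous reports carry no at-risk time). See
the methods vignette (`vignettes/methods.Rmd`) for the statistical
details and design choices.
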