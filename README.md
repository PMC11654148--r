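# faersignal

Disproportionality signal detection for FAERS-style spontaneous report
databases, as a tidyverse-native R pipeline.

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) hold millions of individual case safety reports — a
patient-case with its drugs (and role codes), MedDRA-coded adverse
reactions, seriousness outcomes and demographics — but no denominator, so
drug risk cannot be estimated directly. Pharmacovigilance instead screens
for *disproportionality*: drug–event pairs reported more often than the
database margins predict. faersignal is for pharmacoepidemiologists and
drug-safety analysts who want that screen as reproducible code: it parses
the public FAERS quarterly extract layout, deduplicates multi-version
cases, cohorts a target primary-suspect drug, and flags signals at
preferred-term (PT) and system-organ-class (SOC) level, with a
combination-therapy comparator analysis and a Table-1-style demographics
summary. A fully seeded synthetic-data generator produces FAERS-shaped
databases with planted associations of known strength, so the entire
pipeline is testable offline with ground truth.

## The statistics

For a drug–event 2×2 table — `a` reports of the event in the target-drug
cohort, `b` other target-cohort reports, `c` and `d` the same in the
background — the package computes the reporting odds ratio

    ROR = ad / bc,    95% CI = ROR · exp(±1.96 √(1/a + 1/b + 1/c + 1/d))

and the Bayesian information component

    IC     = log2((N_obs + 0.5) / (N_exp + 0.5)),   N_exp = N_drug · N_effect / N_total
    IC025  = IC − 3.3 (N_obs + 0.5)^−1/2 − 2   (N_obs + 0.5)^−3/2
    IC975  = IC + 2.4 (N_obs + 0.5)^−1/2 − 0.5 (N_obs + 0.5)^−3/2

A term is a **signal** when ROR025 > 1, IC025 > 0 and a ≥ 4. The
combination-therapy screen (target drug + immune checkpoint inhibitor
versus a configurable comparator regimen) uses the ROR only, with
ROR025 > 1 and a ≥ 4. Zero cells get the Haldane–Anscombe 0.5 correction
(ROR only, flagged in the output); no multiplicity adjustment is applied,
by design. See the methods vignette
(`vignettes/faers-disproportionality.Rmd`) for assumptions and numerical
choices.

## Worked example

Simulate a 50,000-report database in which 2% of reports carry the target
drug as primary suspect and two reactions are planted at 8× and 3× their
2% baseline reporting probability, then run the screen:

```r
library(faersignal)

cfg <- synthetic_config(n_reports = 50000, target_drug_prob = 0.02,
                        planted = c(INJECTION_SITE_NECROSIS = 8, SEPSIS = 3),
                        seed = 2024)
sim <- simulate_faers(cfg)

db <- sim$quarters |>
  deduplicate_cases() |>
  cohort_primary_suspect(cfg$target_drug_name)
db
#> <faers_db> 50000 case reports (89402 drug rows, 78383 reactions, 38247 outcomes)
#>   cohorted: 991 target / 49009 background

sig <- detect_signals(db, level = "pt", map = sim$pt_soc_map)
dplyr::filter(tidy(sig), signal)
#> # A tibble: 2 × 8
#>   term                    soc        n   ror ror025 ror975    ic ic025
#>   <chr>                   <chr>  <int> <dbl>  <dbl>  <dbl> <dbl> <dbl>
#> 1 INJECTION_SITE_NECROSIS SOC_01   230  9.05   7.74  10.6   2.66  2.44
#> 2 SEPSIS                  SOC_02    87  2.89   2.30   3.62  1.38  1.03
```

Exactly the two planted terms are flagged out of 50 tested. The ROR
estimates sit near each planted term's design odds ratio
((λp/(1−λp))/(p/(1−p)): 9.3 for λ = 8, 3.1 for λ = 3 at p = 0.02), `n` is
the deduplicated case count, and the confidence/credibility bounds drive
the signal rule. `glance(sig)` reports the screen's metadata (terms
tested, cohort sizes, thresholds, counting unit), `autoplot(sig)` draws
the forest plot, and `summarize_demographics(db)` tabulates the cohort:

```r
summarize_demographics(db)
#> <faers_demographics> total = 991 reports
#> # A tibble: 19 × 4
#>   section           label                 n   pct
#>   <chr>             <chr>             <int> <dbl>
#> 1 Sex               Female              395  39.9
#> 2 Sex               Male                353  35.6
#> 3 Sex               Unknown             243  24.5
#> 4 Reporting country USA                 672  67.8
#> ...
```

`run_faers_analysis(faers_run_config(...))` chains every stage (read →
dedup → cohort → SOC and PT screens → exclusion-list filter → combination
analysis → demographics) from files on disk to written result tables with
a per-stage run log; `inst/cli/faersignal.R` wraps `simulate` and
`analyze` for shell use. Real FAERS quarters are read with
`read_faers_dir()`; you supply the PT→SOC map (MedDRA is licensed and not
bundled) and the drug synonym lists.

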