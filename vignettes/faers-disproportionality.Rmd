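---
title: "Disproportionality signal detection for FAERS-style databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for FAERS-style databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect individual case safety reports (ICSRs): one patient-case,
its drugs with role codes (primary suspect `PS`, secondary suspect `SS`,
concomitant `C`, interacting `I`), its adverse reactions coded as MedDRA
preferred terms (PTs), and its seriousness outcomes. Because reporting is
voluntary and has no denominator, risk cannot be estimated directly;
instead, *disproportionality analysis* asks whether a drug–event pair is
reported more often than the database margins predict. faersignal
implements that screen end to end for FAERS quarterly extracts or for
synthetic databases shaped like them.

The pipeline is: parse the dollar-delimited DEMO/DRUG/REAC/OUTC quarter
files; collapse multi-version cases to one report each; split the database
into a target-drug cohort and background; tabulate drug–event 2×2 tables at
PT and system-organ-class (SOC) level; estimate the reporting odds ratio
(ROR) and the Bayesian information component (IC); apply a conjunctive
signal rule; and, separately, compare combination therapy (target drug plus
an immune checkpoint inhibitor) against a comparator regimen.

## Case deduplication

A FAERS case (`caseid`) can be submitted repeatedly as follow-up versions,
each with its own `primaryid`. Counting versions as cases would bias every
count downstream, so `deduplicate_cases()` keeps, per `caseid`, the row
with the highest `caseversion` across all quarters supplied, and attaches
drug, reaction and outcome rows from that retained `primaryid` only.
Missing `caseversion` (seen in legacy-format quarters) is treated as
version 1; the same max-version rule is applied uniformly to all quarters.
Ties at the same `caseversion` are broken by the latest FDA receipt date
and then by the lexicographically largest `primaryid` — an arbitrary but
deterministic order that keeps re-runs byte-identical. The dedup audit
reports versions in, cases out and duplicates removed.

Ages arrive as a value plus a unit code; `convert_age()` converts decades,
years, months, weeks, days and hours to years, treats a missing unit as
years, and sets results outside [0, 150] years to missing rather than
propagating implausible values.

## Cohorting

A report enters the target cohort when at least one drug row matches a
user-supplied synonym list *and* carries the `PS` role; everything else is
background. Matching is exact after normalisation (trim, collapse internal
whitespace, uppercase) against both the verbatim drug name and the
active-ingredient field. No fuzzy matching is attempted: free-text drug
name cleaning is a hard problem in its own right, and exact matching on a
curated synonym list is reproducible.

## The statistics

For a term with 2×2 cells `a` (target cohort, event present), `b` (target
cohort, event absent), `c` (background, present), `d` (background, absent):

$$ROR = \frac{ad}{bc},\qquad
CI_{95\%} = ROR \cdot e^{\pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}}$$

$$IC = \log_2\frac{N_{obs}+0.5}{N_{exp}+0.5},\qquad
N_{exp} = \frac{N_{drug}\,N_{effect}}{N_{total}}$$

with closed-form 95% credibility bounds

$$IC_{025} = IC - 3.3\,(N_{obs}+0.5)^{-1/2} - 2\,(N_{obs}+0.5)^{-3/2}$$
$$IC_{975} = IC + 2.4\,(N_{obs}+0.5)^{-1/2} - 0.5\,(N_{obs}+0.5)^{-3/2}$$

A term is a **signal** when ROR~025~ > 1, IC~025~ > 0 and `a >= 4`
(`min_a` is configurable). The IC's shrinkage term makes it conservative at
small counts; the ROR is the familiar, transparent measure; requiring both,
plus a minimum case count, guards against signals driven by a handful of
reports. The combination-therapy screen uses the ROR only, with the rule
ROR~025~ > 1 and `a >= 4`.

Numerical choices:

* **Counting unit.** The default 2×2 is report-level — `b` is "target
  reports without the event", so `a+b+c+d` equals the number of reports in
  the database and the IC margins are consistent with the ROR table. This
  is the dominant convention for FAERS disproportionality. Pair-level
  counting (report–term pairs as the unit) is available as
  `counting = "pair"` for comparison with analyses that tabulate events
  rather than reports.
* **Zero cells.** The ROR is undefined when a cell is zero, so the
  Haldane–Anscombe correction (0.5 added to all four cells) is applied to
  those tables only, and flagged in `zero_cell_corrected`. The IC needs no
  correction: the +0.5 shrinkage is part of the formula, and
  `N_obs = N_exp = 0` gives IC = 0 with wide, asymmetric bounds.
* **Multiplicity.** No multiple-testing adjustment is applied; the
  conjunctive threshold rule *is* the decision rule, as is standard for
  hypothesis-generating pharmacovigilance screens. This is recorded in the
  output metadata and is a known limitation: across hundreds of terms some
  false signals are expected, which is why screens feed clinical review
  rather than replace it.
* **z.** Fixed at 1.96 (two-sided 95%) by default, configurable for
  sensitivity analyses.
* **Ordering.** Result tables are sorted by SOC, then descending case
  count, then term, so output order is deterministic.

## SOC rollup

MedDRA is licensed, so the package ships no terminology. The user supplies
a two-column `pt, soc` table giving each PT's primary SOC; conflicting
duplicate mappings are a hard error, and PTs missing from the map are
routed to the sentinel SOC `UNMAPPED` rather than dropped. At SOC level
the counting unit is the report: a report with three PTs in one SOC adds 1
to that SOC's `a`. Per-PT-occurrence counting at SOC level would count
sicker patients (more PTs per report) several times and break the
`a + b + c + d = N` identity, so it is not offered at SOC level; pair-level
counting at PT level covers the occurrence-style analysis.

## The combination-therapy comparator

To ask whether an event is differentially reported when the target drug is
combined with an immune checkpoint inhibitor (ICI), the exposure group is
target-cohort reports that also list the ICI in any role. Two comparators
are defensible and both are implemented:

* `other-target-regimens` (default): target-cohort reports *without* that
  ICI — the target drug in other regimens, including monotherapy. This
  isolates the ICI's contribution within the target-drug population.
* `other-ici-regimens`: reports listing the ICI but outside the target
  cohort — the ICI's own background. This asks instead whether the
  combination exceeds the ICI's usual reporting profile.

The two answer different questions and can disagree; the mode is recorded
in the result attributes and the run manifest.

## Demographics

`summarize_demographics()` tabulates sex, reporting country (collapsed to
USA / Rest of the world / Unknown), reporting year (FDA receipt year of the
retained version — FAERS event dates are too often missing to be the
primary choice), age bands and seriousness outcome. Outcome codes are made
mutually exclusive by a severity precedence (Death > Life-threatening >
Hospitalization > Disability > Other serious, with `CA`/`RI`/`OT` all
"Other serious events"; no code at all is "Unknown"), so each section's
counts sum exactly to the cohort total and percentages are
`round(100 n / total, 1)`. Age bands are half-open, `[45, 60)` printed as
"45 ~ 59 years", so a 59.9-year-old falls below the boundary and a
60.0-year-old above it.

## The synthetic generator

`simulate_faers()` exists so the entire pipeline is testable offline with
known ground truth. Per report it draws: Bernoulli target-drug exposure
(default 1%); per-PT Bernoulli reaction inclusion at a baseline probability
(default 2% per PT over a 50-PT, 10-SOC toy ontology); demographics, with
per-field missingness (defaults: sex 25%, age 35%, country 5%, receipt
date 1%, roughly the missingness seen in published FAERS cohort tables);
seriousness outcomes (defaults 10% death, 2% life-threatening, 21%
hospitalisation, 1% disability, 38% other serious, 28% none); 0–2
concomitant background drugs; and ICI co-medication at configurable rates.
Reports that would carry no reaction are redrawn until they have at least
one, since reaction-free reports cannot enter a reporting-rate analysis. A
configurable fraction of cases (default 10%) is emitted in 2–4 versions
with perturbed earlier-version reaction lists, exercising deduplication;
the highest version is the ground truth, and the truth table records the
exact realised 2×2 cells per PT among final versions.

**Planting.** A planted association multiplies the baseline PT probability
within target reports: `p -> min(1, lambda * p)`. The design estimand of
the screen is then the odds ratio
$\frac{\lambda p/(1-\lambda p)}{p/(1-p)}$, which tends to $\lambda$ as
$p \to 0$ but sits above it at finite baselines — for $\lambda = 5$ and
$p = 0.02$ it is 5.44, and the package's recovery tests are read against
that analytic value. This probability-scale planting was chosen because it
keeps the generator a one-line mechanism with a closed-form expectation;
conditioning on at least one reaction per report shifts the estimand by
well under 1%.

What the generator deliberately does **not** emulate: real MedDRA
vocabulary or hierarchy depth, reporting trends over time, correlated
reactions (syndromes), drug–drug interaction effects, free-text drug-name
noise, or country-specific reporting cultures. Passing tests on synthetic
data therefore demonstrate that the *procedure* is correct — parsing,
deduplication, counting, estimation, thresholding — not that the screen's
operating characteristics on real FAERS data match the simulation.

## Determinism and problem sizes

Everything downstream of the generator is deterministic; the generator
itself is fully seeded and restores the caller's RNG state, so a config
plus seed reproduces the quarter files byte for byte, and re-running the
pipeline on the same inputs reproduces every output table byte for byte.

The test suite validates the estimators against an independently coded
direct-formula evaluator on 1,000 random tables (agreement to 1e-12
relative error), checks deduplication against a brute-force per-case
argmax on generated fixtures, verifies truth-table/pipeline agreement
cell-for-cell at 5,000 reports across several seeds, and measures planted
signal recovery at 100,000 reports across 20 seeds — sizes chosen so the
sampling error of the recovery checks is small relative to the effects
being recovered while the whole suite stays quick on a laptop.

## Limitations

Disproportionality screens generate hypotheses, not causal claims;
reporting odds ratios are not incidence ratios. The package applies no
multiplicity control, no LLT-to-PT normalisation, no SMQ groupings, no
probabilistic record linkage beyond the caseid/version rule, and no
curation of indication-related terms (an exclusion list is applied verbatim
if the user supplies one; an annotated example ships in
`inst/extdata/example_exclusion_terms.txt`). EBGM/MGPS and full Bayesian
BCPNN posteriors are out of scope — the IC here is the closed-form
approximation only.
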