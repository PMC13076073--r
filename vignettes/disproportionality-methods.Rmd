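---
title: "Disproportionality signal detection for spontaneous-report databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous-report databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntary adverse-event
reports, each listing the drugs involved (with role codes: primary suspect,
secondary suspect, concomitant, interacting) and the observed reactions as
MedDRA preferred terms (PTs). There is no denominator: we never observe how
many people took a drug, only how often drug-event pairs are *reported*.
Disproportionality analysis therefore asks a purely relative question: is
this event reported more often with this drug than with everything else in
the database?

`pvsignal` implements that analysis end to end: a synthetic report
generator with known ground truth, curation (name normalization,
structural validation, deduplication), suspect-role-aware case selection,
2x2 contingency construction, and a multitiered panel of
disproportionality statistics with a joint frequentist/Bayesian signal
rule.

## The 2x2 table and the statistical panel

Every statistic derives from the report-level table for one (drug query,
endpoint) pair:

|              | event          | no event |
|--------------|----------------|----------|
| **query**    | a              | b        |
| **other**    | c              | d        |

with N = a + b + c + d the curated database size. The panel computed by
`signal_stats()`:

* **Reporting odds ratio**, ROR = ad / bc, with the Woolf 95% interval
  exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d)). If any cell is zero the ROR
  is reported *not estimable* (`NA`, rendered `NE`); a Haldane-style +0.5
  continuity mode exists behind `continuity = TRUE` but is off by default,
  because zero-count combinations are conventionally published as not
  estimable rather than corrected.
* **Proportional reporting ratio**, PRR = [a/(a+b)] / [c/(c+d)], and
  **relative reporting ratio**, RRR = aN / ((a+b)(a+c)) — the
  observed-to-expected count ratio. Secondary validation metrics.
* **Yates chi-square**, N(|ad−bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d)), floored
  at zero when |ad−bc| ≤ N/2. Used only inside the Evans screen.
* **Fisher exact p**: two-sided, by full hypergeometric enumeration with
  the minimum-likelihood convention — sum the probabilities of all tables
  (margins fixed) no more probable than the observed one, with a relative
  tolerance of 1e-7 on that comparison. We use the exact test as the
  association p because small and zero cells are routine in
  pharmacovigilance (a co-reporting query can legitimately return two
  cases); the chi-square approximation is unreliable exactly there.
* **Information component**, IC = log2((a + 0.5)/(E + 0.5)) with
  E = (a+b)(a+c)/N. The +0.5 is Bayesian shrinkage toward the
  database-wide reporting mean: it keeps the IC finite at a = 0 and damps
  the small-count volatility that notoriety spikes and early
  post-marketing reporting waves (the Weber effect) otherwise amplify.
  **IC025**, the 2.5% credibility bound, is by default the exact quantile
  log2(G/(E + 0.5)) with G ~ Gamma(a + 0.5, rate 1); the widely used
  closed form IC − 3.3(a+0.5)^(−1/2) − 2(a+0.5)^(−3/2) is available as
  `ic_mode = "approx"` and agrees with the quantile mode within 0.15 for
  a ≥ 1 (asserted over an exhaustive sweep in the tests).
* **Evans criteria**: n > 2, chi-square > 4, ROR > 2 (all strict). The
  classical screen uses the PRR; we screen the ROR by default to match the
  multitiered framework this package mirrors, with `evans_metric = "prr"`
  as an option.

A pair is classified **SIGNAL** when p < 0.05 *and* IC025 > 0 (both
strict); **NOT_ESTIMABLE** when no case was observed and the ROR is not
estimable; **NO_SIGNAL** otherwise. Requiring both a frequentist and a
shrunk Bayesian criterion is deliberately conservative: a small-count pair
can reach p < 0.05 while its shrunk IC025 stays negative, and such pairs
are not called signals. No multiplicity adjustment is applied across
pairs; the run metadata states this prominently.

## Case selection

A `drug_query()` fixes the exposed side of the table. Two modes mirror the
two study designs the pipeline supports: `"primary_suspect"` counts only
reports naming a query drug as PS (accurate attribution), `"any_role"`
counts any mention (maximum sensitivity; required for combination queries,
where every query drug must co-occur on the report). Matching is at report
level — a drug mentioned twice counts once — and the comparator is always
*all other reports in the curated database*, not a comparator drug class.
Endpoints match reaction PTs by exact case-folded string equality; no
MedDRA hierarchy traversal is attempted, since endpoints here are small
explicit PT lists.

One open design point: whether a single-drug query should exclude reports
that also mention the *other* study drug. The default excludes nothing;
the handful of co-reports is negligible against thousands of single-drug
reports, and exclusion semantics can be obtained by adding a query with
`combination = TRUE` and comparing.

## Curation

* **Normalization** maps case-folded, trimmed verbatim names (brands,
  salts, abbreviations) to canonical lower-case names through a
  user-supplied synonym table; unmapped names are flagged `unresolved` and
  *retained* — they still belong in the comparator denominator.
* **Validation** excludes reports with a missing receipt date or one
  outside the closed analysis window (default 2003-12-01 to 2024-12-31,
  the month-boundary window read as full calendar days), an empty drug
  list, an empty reaction list, or a negative age. Each exclusion is
  tallied under exactly one reason in the fixed precedence date → drugs →
  reactions → demographics, so curation reports are deterministic.
* **Deduplication** groups reports by `case_id` when shared (versions of
  one case) and otherwise by the tuple (sex, age rounded to whole years,
  country, sorted normalized drug names, sorted case-folded reaction PTs).
  Age is rounded to tolerate unit jitter between re-submissions, and a
  missing age matches another missing age (a re-submission that omitted
  age again must still be catchable). Within a
  group the latest receipt date wins, ties broken by smallest `report_id`.
  Because the key is a finite tuple, distinct minimal reports (one common
  drug, one common reaction, same demographic cell) can genuinely
  collide at database scale; such removals are legitimate under the rule
  and the audit table `removed` lets them be checked against ground
  truth.
  The matched-variables rule and keep-latest tie-break are declared
  conventions: source systems describe *that* demographic and case-level
  variables are matched, not the exact rule, and determinism demands one.

The combined report satisfies n_input = n_output + n_excluded_invalid +
n_removed_duplicates on every run (asserted in the tests).

## The synthetic generator

`simulate_faers()` draws databases whose ground truth is known, so every
downstream stage is testable without a live database. Per report: a
receipt date uniform in the window; age, sex, country from fixed
plausible marginals (8% of ages missing); each catalog drug included
independently with its marketing probability, one mention uniformly
chosen as primary suspect, other mentions assigned SS/C/I; each catalog
PT included independently with probability
logit⁻¹(logit(baseline) + Σ ln θ) over the report's drugs with a planted
effect on that PT. Under this per-PT independent Bernoulli model with
log-odds additive effects a planted multiplier θ *is* the true reporting
odds ratio, which makes parameter recovery well-defined rather than
approximate.

Fillers keep every primary report structurally valid without touching the
calibration of catalog frequencies: a report whose draws yield no drug
receives one mention (as PS) sampled from a pool of twenty common drug
names, and one with no catalog PT receives one term from a pool of thirty
common PTs — both pools disjoint from the catalogs, so catalog marginals
stay exactly Bernoulli (the tests assert each PT frequency within three
Monte-Carlo standard errors of its baseline at n = 50,000 under the
null). Sampling fillers from pools rather than using one constant name
matters for deduplication: minimal one-drug/one-reaction reports then
spread across many key tuples instead of colliding wholesale, as they
would if every such report looked identical.

Contamination is exact-count: round(duplicate_rate · n) near-duplicate
clones (identical demographics, drugs, reactions; new report and case
ids; receipt date shifted forward up to 30 days, clamped to the window)
and round(invalid_rate · n) corrupted copies (drug list emptied, reaction
list emptied, or age set negative). The defaults used in the worked
examples, 5% duplicates and 2% invalid, are fixture choices representative
of raw spontaneous-report extracts, not estimates of any real database's
contamination. Random numbers are consumed in a fixed, documented order,
so a seed pins the database byte for byte.

The default catalog plants the study-shaped pattern: a mood stabiliser
with θ between 4 and 9.5 on five renal PTs, a GLP-1 comparator with θ
between 0.25 and 0.96 on the same PTs, and six high-volume background
drugs with no effects. Marketing probabilities (1% for the study drugs)
and renal baselines (0.4–3%) were chosen so that a study-sized simulation
(n = 200,000) yields a few hundred cases per endpoint — enough that the
standard error of ln ROR (≈ 0.06 for the planted θ = 8 pair) supports
recovery of the planted value within ±1 on the ratio scale.

What the generator does *not* emulate: reporting dynamics over time
(Weber effect, notoriety spikes), country-specific reporting propensity,
correlated reaction terms, free-text noise beyond the synonym map, and
multi-version case threading beyond shared `case_id`s. Passing tests
therefore demonstrate correctness of the statistical machinery and the
curation rules under a clean generative model — not robustness to every
messiness of a live pharmacovigilance database.

## Numerical and testing choices

* Cells are coerced to doubles before products: ad with FAERS-scale
  counts overflows 32-bit integers.
* The Fisher p is compared against two independent oracles: a log-space
  hypergeometric enumeration over every table with N ≤ 60 (635,376
  tables, by stars and bars), and `stats::fisher.test` on 2,000 random
  tables with N ≤ 200. The arithmetic statistics are swept exhaustively
  over all tables with cells ≤ 30.
* Recovery and calibration properties run at the study size n = 200,000
  over 100 seeds: planted θ = 8 recovered with point ROR in [7, 9] and a
  SIGNAL call in ≥ 90% of seeds; under the null, SIGNAL rate within
  Monte-Carlo noise of the nominal level and Woolf interval coverage of
  θ = 1 within 0.95 ± 3 SE.
* All outputs are deterministic given inputs: repeated runs write
  byte-identical CSVs, with no timestamps in any output file.

## Limitations

Disproportionality measures reporting, not risk: no denominator, no
causality, confounding by indication and channeling remain. An IC025
below zero is an absence of disproportionality, never evidence of
protection. The package's scope is the reporting-pattern machinery; any
clinical interpretation belongs to patient-level studies.
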