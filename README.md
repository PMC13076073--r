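# pvsignal

Disproportionality signal detection for spontaneous adverse-event report
databases, built tidyverse-style: tibbles in, tibbles out, `tidy()` /
`glance()` / `autoplot()` on the run object.

Spontaneous reporting systems (FAERS and its siblings) collect voluntary
adverse-event reports — drugs with role codes, reactions as MedDRA
preferred terms, demographics — with no exposure denominator. The only
well-posed question is relative: *is this event reported
disproportionately often with this drug compared with everything else in
the database?* `pvsignal` implements the full analysis pipeline for that
question, aimed at pharmacoepidemiologists and methodologists who want a
reproducible, testable desk-scale counterpart to platform tools:

* **`simulate_faers()`** — a synthetic report generator with planted
  drug–event reporting-odds multipliers θ (per-PT Bernoulli, log-odds
  additive, so the planted θ *is* the true reporting odds ratio),
  configurable near-duplicate and invalid-record contamination, brand and
  generic name variants, and full ground truth.
* **`curate()`** — drug-name normalization against a synonym map,
  structural validation with a fixed exclusion-reason precedence, and
  case deduplication (shared `case_id`, else a demographic + drug + PT
  key tuple; latest report kept). Conservation always holds:
  n_input = n_output + excluded + removed.
* **`drug_query()` / `build_contingency()`** — suspect-role-aware case
  selection (primary-suspect-only or any-role; combination queries) over
  preferred-term endpoints, producing the report-level 2×2 table
  (a, b, c, d) against all other reports.
* **`signal_stats()`** — the multitiered panel on each table:

  | statistic | definition |
  |---|---|
  | ROR (95% CI) | ad/bc, Woolf interval exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)) |
  | PRR | [a/(a+b)] / [c/(c+d)] |
  | RRR | aN / ((a+b)(a+c)) |
  | χ² (Yates) | N(\|ad−bc\|−N/2)² / ((a+b)(c+d)(a+c)(b+d)) |
  | p | two-sided Fisher exact, full hypergeometric enumeration |
  | IC, IC025 | log₂((a+½)/(E+½)), exact Gamma-posterior 2.5% quantile |
  | Evans | n > 2 ∧ χ² > 4 ∧ ROR > 2 |

  A pair is a **SIGNAL** iff p < 0.05 and IC025 > 0; zero-case pairs are
  reported **NOT_ESTIMABLE**, never dropped.
* **`run_pipeline()`** — curation → queries → statistics for a configured
  set of labelled queries and endpoints, with deterministic CSV/JSON
  outputs and a forest plot (`autoplot()`).

## Worked example

Simulate a 20,000-report database with the study-shaped defaults — a
nephrotoxic mood stabiliser (θ = 4–9.5 across five renal PTs), a GLP-1
comparator with inverse reporting (θ = 0.25–0.96), 5% duplicate and 2%
invalid contamination — then curate and analyse it:

```r
library(pvsignal)

cfg <- default_sim_config(n_reports = 20000, seed = 42,
                          duplicate_rate = 0.05, invalid_rate = 0.02)
sim <- simulate_faers(cfg)
run <- run_pipeline(run_config(sim$db))
run
#> <pv_run> 3 queries x 5 endpoints on 19515 curated reports
#> # A tibble: 15 × 7
#>    label               endpoint        a     ror  p_value   ic025 classification
#>    <chr>               <chr>       <int>   <dbl>    <dbl>   <dbl> <chr>
#>  1 lithium             Renal impa…    18   7.99  1.52e-10   1.82  SIGNAL
#>  2 lithium             Renal fail…    13   4.01  5.67e- 5   0.856 SIGNAL
#>  3 lithium             Chronic ki…     7   3.37  6.46e- 3   0.224 SIGNAL
#>  4 lithium             End-stage …     2   2.96  1.53e- 1  -1.52  NO_SIGNAL
#>  5 lithium             Acute kidn…    34   8.00  6.19e-18   2.02  SIGNAL
#>  6 semaglutide         Renal impa…     2   0.860 1   e+ 0  -2.76  NO_SIGNAL
#>  7 semaglutide         Renal fail…     2   0.634 7.73e- 1  -3.12  NO_SIGNAL
#>  8 semaglutide         Chronic ki…     1   0.513 1   e+ 0  -4.49  NO_SIGNAL
#>  9 semaglutide         End-stage …     1   1.64  4.60e- 1  -3.37  NO_SIGNAL
#> 10 semaglutide         Acute kidn…     2   0.406 2.46e- 1  -3.67  NO_SIGNAL
#> 11 lithium+semaglutide Renal impa…     0  NA     1   e+ 0 -10.1   NOT_ESTIMABLE
#> 12 lithium+semaglutide Renal fail…     0  NA     1   e+ 0 -10.2   NOT_ESTIMABLE
#> 13 lithium+semaglutide Chronic ki…     0  NA     1   e+ 0 -10.1   NOT_ESTIMABLE
#> 14 lithium+semaglutide End-stage …     1 120.    1.26e- 2  -2.25  NO_SIGNAL
#> 15 lithium+semaglutide Acute kidn…     0  NA     1   e+ 0 -10.3   NOT_ESTIMABLE
```

Reading the output: the primary-suspect lithium query shows elevated
reporting odds on every renal endpoint and clears the joint signal rule
on four of five (the rare end-stage endpoint has only 2 cases at this
database size — p and IC025 both miss, so no signal is called). The
semaglutide query sits at or below ROR 1 with uniformly negative IC025 —
an *absence of disproportionality*, which is not evidence of protection.
The combination query has almost no co-occurring reports: zero-case
endpoints are reported as `NOT_ESTIMABLE`, and the one-case rows show why
small-count pairs need the Bayesian bound — a huge ROR with p < 0.05 is
still shrunk to IC025 < 0 and correctly not called a signal.

```r
glance(run)
#> # A tibble: 1 × 8
#>   n_input n_excluded_invalid n_removed_duplicates n_curated n_pairs n_signal …
#> 1   21400                400                 1485     19515      15        4
tidy(run)       # the full 15-row statistics table
autoplot(run)   # forest plot, one panel per query, log axis, ROR = 1 line
```

`run_config(..., output_dir = "out")` additionally writes `results.csv`
(fixed column order, `NE` for not-estimable cells), `forest.csv`,
`curation_report.json` and `run_metadata.json`.

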