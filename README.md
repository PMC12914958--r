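# pvsignal

Disproportionality signal detection and clinical characterization for
FAERS-style spontaneous adverse-event reports.

Pharmacovigilance studies of a drug–event pair — the motivating case is
serious neutropenia reported under pembrolizumab — follow a standard chain:
read the quarterly entity tables, keep only the latest version of each
safety report, restrict to serious reports with the drug as Primary
Suspect, define the event cohort at the MedDRA Preferred-Term level,
quantify disproportionate reporting against the database background,
derive time-to-onset, and characterize the cohort clinically. `pvsignal`
implements that chain as composable, tested R functions, plus a synthetic
report generator with planted ground truth so every stage can be validated
without access to the live database.

## The statistics

All signal statistics derive from the 2×2 table over the deduplicated
serious-report corpus — `a` target event with the drug as Primary Suspect,
`b` other events with the drug, `c` the event under other drugs, `d`
everything else:

- **ROR** = ad/bc with log-Wald 95% CI
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)); signal if the lower bound > 1.
- **PRR** = [a/(a+b)]/[c/(c+d)] with the Yates-corrected Pearson χ²;
  signal if PRR ≥ 2, a ≥ 3 and χ² ≥ 4.
- **IC** = log₂((a+0.5)/(E+0.5)) with E = (a+b)(a+c)/N and gamma-quantile
  95% credibility bounds; signal if the lower bound > 0.
- **EBGM** from the multi-item gamma-Poisson shrinker: a two-gamma mixture
  prior on the relative reporting ratio fitted by maximum marginal
  likelihood over all drug–event pairs, posterior geometric mean in closed
  form, percentiles by root-finding on the mixture CDF; signal if
  EBGM05 > 2.

Time-to-onset is derived hierarchically (date difference, else treatment
duration × unit factor), summarized by median/IQR and cumulative onset
proportions, and compared between concomitant-chemotherapy subgroups with
the Mann-Whitney U test (exact enumeration for small groups, tie-corrected
normal approximation otherwise).

## Worked example

An end-to-end run on a synthetic corpus of 50,000 reports with a planted
reporting-rate ratio of 5 for the pair PEMBROLIZUMAB–Neutropenia:

```r
library(pvsignal)

cfg <- synthetic_config(n_reports = 50000, seed = 42)
res <- run_pipeline(run_config(synthetic = cfg, out_dir = "demo-run"))
#> ingest: 55000 raw demo rows
#> deduplicate: 55000 -> 50000 reports
#> serious_filter: 33563 serious reports
#> ps_cohort: 3479 primary-suspect serious reports
#> signal: a=310, ROR=5.55
#> pt_cohort: 310 reports with PT 'Neutropenia'
#> tto: 109 evaluable onsets
#> tto: median chemo 16.4 vs no-chemo 40.1 d (U=719, p=0.002512)
#> fn_supplement: 85 reports, 87.1% with concomitant chemotherapy
```

The 55,000 raw rows shrink to 50,000 reports because 10% of cases were
emitted twice as case versions; deduplication keeps the latest version.
The four statistics for the planted pair:

```r
res$signal[, c("ror", "ror_lo95", "ror_hi95", "prr", "chi2", "ic", "ebgm", "ebgm05")]
#> ROR 5.55 (4.80-6.42)  PRR 5.15 (chi2 662.6)  IC 1.84 (1.68-2.00)
#> EBGM 2.42 (EB05 2.22)
```

The ROR interval covers the planted ratio (its estimand, the implied odds
ratio, is 5.25 — see `ground_truth(cfg)`). EBGM is deliberately the most
conservative: on a compact synthetic pair universe the empirical-Bayes
prior concentrates near 1 and shrinks a lone outlying pair hard. The onset
analysis recovers the planted group difference (log-normal medians 14.5 vs
39 days):

```r
res$tto_summary$median     # 20.0 days overall (IQR 10.0-40.1), n = 109
res$comparison             # U = 719 (chemo group), two-sided p = 0.0025
```

Per-stage tables (signal table, stratified ROR, demographics, outcomes,
ranked indications/concomitants, onset observations and summary, the
febrile-neutropenia supplement) are written tab-separated to `out_dir`
together with a JSON manifest of row counts and file hashes; re-running the
same configuration is byte-identical. A thin command-line wrapper is
installed at `inst/cli/pv-run.R` for shell use with a key-value config
file.

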