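---
title: "Methods: disproportionality signal detection and onset analysis for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and onset analysis for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## Scope

`pvsignal` implements the standard analysis chain used in pharmacovigilance
studies of a single drug–event pair in a spontaneous-report database such as
FAERS: ingest quarterly entity tables, keep the latest version of each safety
report, build a primary-suspect serious-event cohort at the MedDRA
Preferred-Term (PT) level, quantify disproportionate reporting with four
algorithms (ROR, PRR, IC, EBGM), derive time-to-onset (TTO) hierarchically,
and characterize the cohort clinically. A synthetic report generator with
known ground truth makes the whole chain testable without database access.
The motivating use case is serious neutropenia under pembrolizumab, with
concomitant cytotoxic chemotherapy as the key effect modifier.

## Data model and deduplication

Reports are held as a list of typed tables (`demo`, `drug`, `reac`, `outc`,
plus therapy and indication rows joined onto drug entries) keyed by
`(caseid, caseversion)`. Spontaneous reports are re-submitted as new case
versions; only the latest is analytically valid. The retained version per
case id is the maximum under the lexicographic order *(case version, receipt
date, file order)*. "Latest version" alone is ambiguous when a version
number is reused, so the receipt date resolves version ties and file order
resolves exact ties (with a warning); this makes deduplication deterministic
and idempotent.

Free-text drug and indication fields are normalized before any counting:
uppercase, strip characters outside `[A-Z0-9 ]`, collapse whitespace, then
map synonyms (brand names of the fourteen-drug chemotherapy panel ship with
the package). Stripping happens before the synonym lookup, so map keys are
cleaned strings; the shipped map's values are fixed points, which keeps
normalization idempotent. Intra-word digits survive, so names like
"FLUOROURACIL 5" are not mangled.

Dates are parsed as ISO-8601 (also the compact 8-digit form). Year–month
partial dates are resolved to the first of the month and flagged
low-precision rather than dropped — conservative and auditable. Impossible
dates become missing fields with a warning; a row is never dropped for a bad
date.

## Cohorts

The analysis corpus is the deduplicated set of *serious* reports (at least
one FDA seriousness outcome: death, life-threatening, hospitalization,
disability, congenital anomaly, other serious). The drug cohort additionally
requires the target drug as Primary Suspect. Event cohorts are per-PT,
case-insensitive, exact-string — no licensed MedDRA hierarchy is used, and
none is needed for a PT-level analysis. "Febrile neutropenia" is a distinct
PT from "Neutropenia" and forms its own supplementary cohort; a report
listing both PTs belongs to both per-PT cohorts (the cohorts are defined by
PT membership, not partitioned — the alternative assignment rule is a
sensitivity-analysis question, not a default).

Chemotherapy context: a report is "concomitant chemotherapy" if at least one
drug entry with role concomitant *or interacting* matches the fourteen-agent
panel (carboplatin, cisplatin, paclitaxel, docetaxel, nab-paclitaxel,
pemetrexed, gemcitabine, cyclophosphamide, etoposide, fluorouracil,
oxaliplatin, irinotecan, vinorelbine, doxorubicin) after normalization. A
panel drug appearing only as a suspect drug does not count.

## Disproportionality statistics

All four statistics derive from the 2×2 table over the corpus: `a` = target
event with the drug as Primary Suspect, `b` = other events with the drug as
PS, `c` = target event under all other drugs, `d` = everything else. The
comparator is "all other events for all other drugs", i.e. relative
reporting within the database, not comparative risk.

- **ROR** \(= ad/bc\), 95% CI \(\exp(\ln \mathrm{ROR} \pm 1.96\,
  \sqrt{1/a+1/b+1/c+1/d})\). A zero cell leaves it undefined unless the
  Haldane +0.5 correction is explicitly enabled (off by default, flagged in
  output).
- **PRR** \(= [a/(a+b)]\,/\,[c/(c+d)]\), screened with the
  Yates-continuity-corrected Pearson chi-square — the conventional companion
  of the PRR ≥ 2 / χ² ≥ 4 rule; the uncorrected statistic is emitted too so
  either convention can be audited.
- **IC** \(= \log_2 \frac{a + 0.5}{E + 0.5}\) with
  \(E = (a+b)(a+c)/N\), the contemporary shrinkage form of the Bayesian
  confidence propagation statistic; 95% credibility bounds are gamma
  quantiles \(\log_2 q_{\Gamma}(p;\, a+0.5,\, E+0.5)\). The 0.5 constant
  keeps IC defined (and negative) at `a = 0`.
- **EBGM** from the multi-item gamma-Poisson shrinker: the relative
  reporting ratio λ has a five-parameter two-gamma mixture prior fitted by
  maximum marginal likelihood over *all* drug–event pairs in the corpus
  (counts are negative-binomial mixtures given `E`). The posterior for a
  pair is again a two-gamma mixture; EBGM \(= 2^{\mathbb{E}[\log_2 \lambda
  \mid a]}\) in closed form via digamma, and EB05/EB95 come from monotone
  root-finding on the mixture CDF (tolerance 1e-10 on the root). Both the
  90% interval (EB05, EB95) — on which the conventional EBGM05 > 2 criterion
  is defined — and the 95% interval are emitted, since published tables are
  not always explicit about which is printed.

Signal criteria, with boundary strictness exactly as conventionally worded:
ROR lower 95% bound > 1 (strict); PRR ≥ 2 with ≥ 3 cases and χ² ≥ 4 (all
inclusive); IC lower 95% bound > 0 (strict); EBGM05 > 2 (strict).

Numerical choices for the prior fit: bounded quasi-Newton (`L-BFGS-B`) with
all shape/rate parameters in [1e-6, 1e3] and the mixing weight in
[1e-6, 1 − 1e-6], from the standard start (0.2, 0.1, 2, 4, 1/3) plus two
fixed multiplicative jitters of it as restarts. Fixed jitters (rather than
seeded random ones) keep the fit bit-reproducible while still guarding
against local optima; non-convergence of every start is an error carrying
the final gradient norm. At least 100 pairs with positive expectation are
required — empirical-Bayes shrinkage is meaningless on a handful of pairs.
A known behavior worth stating: on corpora with few pairs and large
per-pair counts (such as compact synthetic corpora), the fitted prior is
tight around λ = 1 and EBGM shrinks a single planted signal well below its
raw `a/E`; this is the statistic working as designed, not a defect.

Stratified analyses (sex, by default) recompute all four cells within each
stratum level; reports missing the stratum are excluded from every level
(available-case analysis), and a level with `a = 0` is reported with an
undefined ROR rather than silently dropped.

## Time-to-onset

Per report, TTO is derived hierarchically: (1) if both the suspect drug's
therapy start date and the reaction onset date are present, the plain
difference in days (non-inclusive — whether published analyses add one day
is generally unstated, and the plain difference is the conservative
reading); (2) otherwise the reported treatment duration times a unit factor
(D = 1, WK = 7, MON = 30, YR = 365; calendar-exact factors are not
defensible for free-text duration fields). Non-positive values (same-day
onsets included — a consequence of the "non-positive excluded" rule),
values above the outlier cap (default 1825 days = 5 years, configurable for
sensitivity runs), and unknown unit codes are excluded with a recorded
reason.

Summaries use closest-rank linear interpolation for median and quartiles
(`quantile` type 7) and report cumulative onset proportions at requested day
marks (default 30 and 60). Group comparison uses the Mann-Whitney U test: U
is reported for the first (chemotherapy) group in the rank-sum form
\(R_1 - n_1(n_1+1)/2\); the two-sided p-value is exact by enumeration of
group assignments when the smaller group has ≤ 8 observations (enumeration
handles ties naturally, which is why this is implemented in-package rather
than delegated), and otherwise a tie- and continuity-corrected normal
approximation that matches `stats::wilcox.test` exactly on untied data.

## Clinical characterization

Summaries follow the available-case strategy: every statistic is computed
over the reports where the variable is observed, and that denominator is
reported beside it. Ages are converted to years from their unit codes
(decades ×10, months ÷12) before summarizing. Outcome rows
(hospitalization, life-threatening, death) are *not* mutually exclusive;
each is counted independently over the full cohort, so percentages can sum
past 100. Ranked indication / concomitant-medication lists count reports
(not drug rows), break count ties alphabetically, apply exclusion lists
(e.g. "UNKNOWN INDICATION") before ranking, and attribute indications only
to the suspect drug's own entries. Percentages are computed at full
precision and rounded half-up on the first decimal — base R's banker's
rounding disagrees with conventional table formatting at exact .x5
boundaries (104/856 must print 12.1, not 12.2, and 1/16 must print 6.3,
not 6.2).

## The synthetic generator

`synthetic_config()` / `generate_reports()` emulate the structure of a
serious-report corpus with a planted signal. Defaults are the study
conditions of the motivating cohort:

| knob | default | rationale |
|---|---|---|
| `n_reports` | 20,000 | corpus size at which recovery tests run in minutes |
| `target_drug_frac` | 0.1 | suspect cohort a sizable minority of the corpus |
| `planted_rr` | 5 | reporting-rate ratio of the planted pair |
| `background_event_prob` | 0.0116 | implied by a ~5.8% target event rate at PRR ≈ 5 |
| `chemo_fraction` | 0.83 | share of suspect reports with concomitant chemotherapy |
| `tto_median_chemo` / `_nochemo` | 14.5 / 39.0 d | group onset medians |
| `tto_sigma` | 1 | log-scale spread giving a right-skewed distribution |
| `missing_age_rate` / `missing_sex_rate` | 0.158 / 0.098 | observed missingness levels |
| `missing_date_rate` | 0.45 | applied independently per date field; with the duration-field availability (0.11) this leaves ~37.7% of event reports onset-evaluable |
| `duplicate_rate` | 0.10 | fraction of cases re-emitted as version 2 |

Onsets are log-normal with `exp(meanlog)` equal to the configured group
median — chosen because the family is right-skewed and the median is
controlled in closed form. Duplicated cases perturb exactly one non-key
field (age) and carry a later receipt date, so deduplication correctness is
observable. Sex-specific planted rates (`planted_rr_female`,
`planted_rr_male`) exist for stratified-recovery tests. Fixed internal
constants (not knobs): 51.6% female among reports with sex recorded;
outcome-flag rates set so that rates *conditional on seriousness* match the
motivating cohort (46.6% hospitalization, 12.1% life-threatening, 19.4%
death for event reports, which always carry at least one flag, as any
serious-event cohort does by construction); febrile-neutropenia side-event
rates (2.2% / 1.7% / 0.3%) set so the FN cohort is ~2% of suspect reports
with ~86% chemotherapy share; and small pools of background drugs, PTs,
indications and supportive medications.

Because the event is planted as a reporting *rate* ratio, the estimand of
the ROR is the corresponding odds ratio, slightly above the planted value
(5.25 for a planted 5 at the default background rate); `ground_truth()`
reports both. Recovery tests check coverage of the planted value, which the
Wald intervals absorb at the tested sizes.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: reporting dynamics (Weber effect,
stimulated reporting), realistic drug co-occurrence networks and
polypharmacy, indication-confounded sex differences, PT miscoding and
terminology drift, cross-case duplicate submissions under different case
ids, and non-ignorable missingness (all missingness here is independent per
field). Disproportionality results on real spontaneous reports remain
associations within the database, not comparative risks.

## Problem sizes used in the shipped checks

Unit tests run on corpora of 300–20,000 synthetic reports. The recovery
suite follows the generator's reference conditions: 200 replicates of
20,000 reports for interval coverage (plain and sex-stratified), 10,000
simulated pairs for mixture-prior recovery, and 200 replicates of the
268/55 onset configuration for the power property. The acceptance script
runs one pipeline at 150,000 reports so the event cohort lands near the
scale of a four-year single-drug serious-report cohort (~850 events, ~320
evaluable onsets).

## Known limitations

- PT matching is exact-string; no SMQ/HLT groupings.
- The dedup rule cannot link re-submissions under different case ids.
- The MGPS fit needs a reasonably populated pair universe; compact corpora
  yield heavily shrunken EBGM values.
- The Mann-Whitney exact path enumerates group assignments and is limited
  to small groups (the automatic switch uses it only when the smaller group
  has ≤ 8 observations).
- Multiplicity across PTs is deliberately not adjusted, matching standard
  practice for screening statistics.
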