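---
title: "Signal detection methods in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection methods in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

pvsignal implements an end-to-end disproportionality pipeline for
FAERS-style spontaneous adverse-event reports, built around the analysis of
drug-induced alopecia but applicable to any drug-event question definable
by a preferred-term (PT) list. This vignette documents the models, the
defaults and why they were chosen, the numerical decisions, and what the
synthetic validation does and does not establish.

## Case processing

FAERS publishes quarterly `$`-delimited ASCII tables (DEMO, DRUG, REAC,
THER, OUTC) keyed by `primaryid`. Reports arrive in multiple versions
sharing a `caseid`; following the FDA-recommended rule, `deduplicate()`
keeps the version with the latest FDA receipt date and breaks ties by the
highest `primaryid`. A version with an unparseable receipt date never
displaces a dated one — when an audit date is unavailable we prefer
versions that carry one. De-duplication is idempotent and only ever removes
rows, properties the test suite asserts directly.

Dates in FAERS may carry day, month, or year precision.
`parse_partial_date()` tags the precision and completes partial dates to
the earliest possible day *for ordering only*; day differences (time to
onset) are computed exclusively from day-precision pairs. Ages are
converted to years (`DEC` x10, `YR` x1, `MON` /12, `WK` /52, `DY` /365.25)
and weights to kg (`LBS` x0.4536); values outside 0–130 years or 0–700 kg
are treated as missing rather than propagated. A case is "serious" when it
carries at least one regulatory outcome code (death, life-threatening,
hospitalization, disability, congenital anomaly, required intervention, or
other serious); the dichotomy is not otherwise defined in the source data.

Drug names are normalized by upper-casing and whitespace collapse, with an
optional user-supplied synonym table (brand to generic). No external drug
dictionary is consulted, keeping runs deterministic and offline; free-text
name noise beyond simple synonyms is out of scope.

## Case definition

Target cases are flagged by exact, case-insensitive PT matching against a
Standardized MedDRA Query term list. MedDRA PTs are a controlled
vocabulary, so substring matching would over-match (e.g. "Alopecia" must
not flag "Alopecia areata" entries by containment). The packaged hair-loss
list covers the PTs commonly analysed in alopecia pharmacovigilance
(alopecia, alopecia areata/totalis/universalis, androgenetic and diffuse
alopecia, hypotrichosis, scarring and non-scarring alopecia, injection- and
application-site alopecia, loose anagen syndrome, seborrhoeic alopecia);
MedDRA is licensed and cannot be redistributed, so users of the real SMQ
must load it with `read_smq_csv()`.

Drug attribution is restricted to Primary-Suspect entries by default:
under polypharmacy, counting Secondary-Suspect, Concomitant or Interacting
entries dilutes specificity. Each de-duplicated case contributes at most
once per drug-event cell and no weighting is applied for co-reported
drugs. Drugs indicated for the condition itself (e.g. minoxidil for
alopecia) can be removed after signal evaluation via an exclusion list,
since their disproportionality is confounded by treatment-failure
reporting.

## Disproportionality statistics

All four statistics derive from the standard 2x2 table on de-duplicated
cases: `a` drug+event, `b` drug only, `c` event only, `d` neither.

* **ROR** `= ad/bc`, Woolf interval
  `exp(ln ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Undefined with a zero
  cell; an optional Haldane–Anscombe +0.5 correction (off by default) makes
  it finite. The correction is offered for ROR/PRR only — the Bayesian
  statistics are already shrunk.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Pearson chi-square
  `N(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))`. Yates' continuity correction is
  available behind a flag but off by default; the uncorrected Pearson form
  is the common convention in FAERS studies.
* **BCPNN information component** `IC = log2((a+0.5)/(E+0.5))` with
  `E = (a+b)(a+c)/N`, and the Norén closed-form credibility bound
  `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`. The closed form is
  deterministic and accurate for the decision rule; no Monte-Carlo
  posterior sampling is used.
* **MGPS / EBGM** under DuMouchel's model: counts are Poisson with mean
  `lambda E` and `lambda` has a two-component gamma mixture prior. The five
  hyperparameters are estimated by maximum marginal (negative-binomial
  mixture) likelihood over all drug-event tables, by quasi-Newton
  optimization from four fixed starting points including DuMouchel's
  canonical `(0.2, 0.1, 2, 4, 1/3)`; the best optimum wins. The posterior
  is again a two-gamma mixture, giving
  `EBGM = exp(E[ln lambda | a])` in closed form via digamma, and `EBGM05`
  by root-finding on the posterior mixture CDF (machine-precision `pgamma`,
  tolerance 1e-10). Fewer than ~50 tables triggers a warning: the mixture
  is weakly identified on small panels. Only pairwise drug-event shrinkage
  is implemented; multi-item interaction terms and stratified expected
  counts are out of scope.

A drug is a **positive signal** only when all four methods pass
simultaneously: `a >= 3` with ROR lower bound `> 1`; `a >= 3`, `PRR >= 2`,
`chi2 >= 4`; `IC025 > 0`; `EBGM05 > 2`. These are the conventional criteria
of the FAERS disproportionality literature; every threshold is
configurable via `signal_thresholds()`. An undefined statistic fails its
flag rather than erroring. Volcano statistics (two-sided Fisher exact p,
Bonferroni-adjusted `min(1, m p)`, natural-log ROR) accompany the table.

## Stratification, tiers and label cross-check

Subgroup analyses recompute the 2x2 within each stratum using
stratum-restricted denominators — both the drug's cases and the comparator
come from the stratum. The alternative (whole-database comparators) mixes
populations and was rejected as the default. Age bands are `<18`, `18-44`,
`45-64`, `>=65`, closed on the left; cases missing the stratification field
are excluded from that stratification only. The Bonferroni family is the
number of drugs evaluated *within the stratum* — the most conservative
defensible family — and a drug "loses significance" when its raw Fisher p
is below 0.05 but the adjusted p is not. Within a stratum, drugs with fewer
than 3 cases are skipped by default: their exact tests are uninformative
and dominate runtime.

Risk tiers follow the IC025 boundaries used in signal-prioritization work:
high `IC025 > 3`, medium `1.5 < IC025 <= 3`, low `IC025 <= 1.5`, with
boundary values falling in the lower tier. Label cross-checking consumes a
curated annotation CSV (drug, documented yes/no) rather than retrieving or
text-mining label documents; missing annotations are counted as "unknown".
Percentages round half-up (2 decimals in baseline tables, 1 in the label
cross-tab) at the presentation layer only; raw values are kept in all
outputs.

## Time to onset

Onset is the whole-day difference between the event date and the earliest
Primary-Suspect therapy start for the drug in the case; only day-precision
pairs qualify, and negative differences are excluded with counts logged.
Quartiles use Tukey's median-of-halves convention, so a single record
yields median = Q1 = Q3. Histograms use half-open 30-day bins to 240 days,
then 240–360 and beyond — the bins in which the bimodal latency of
drug-induced alopecia (acute anagen effluvium within a month versus
delayed telogen effluvium at 8–12 months) is conventionally read.

Weibull shape/scale are estimated by maximum likelihood
(`fitdistrplus::fitdist`), with Wald intervals on the log scale and the
median latency `scale * log(2)^(1/shape)`. The Weibull support is positive,
so zero-day onsets — real observations for topical agents — are kept in
summaries and histograms but shifted +0.5 day for the likelihood. Fits
require at least 10 distinct positive values; below that the summary is
still emitted without a fit. Spontaneous reports carry no at-risk
denominators, so no censoring model is attempted. Group comparisons use
the two-sided Wilcoxon rank-sum test: exact enumeration when the combined
n is at most 12 without ties, otherwise the normal approximation with tie
and continuity corrections (which agrees with the exact test within 0.02
by n1 = n2 = 6).

## The synthetic generator

`generate_reports()` emits the five raw tables from a seeded configuration
with known ground truth, emulating the structure of FAERS alopecia case
series: one Primary-Suspect drug per case (a polypharmacy mode adds
non-PS entries that must never enter PS-only indexes), a target-event
probability `min(1, event_base_rate * RR(drug))` with a base rate of 0.008
(the approximate share of alopecia reports in FAERS), sex split
76.82% F / 10.18% M / 13% unknown, ages ~N(53.84, 16.28) truncated to
1–100 with 41.42% missing, 71.53% missing weights, consumer-dominated
reporter occupations, US-dominated regions, receipt years drawn from the
2004–2024 reporting curve (7.5 / 16.2 / 48.3 / 28.0% across the four
bins), per-drug Weibull onset latencies, a configurable fraction of
month/year-precision and missing dates, and duplicate report versions
(older FDA_DT, lower primaryid) that de-duplication must resolve.

The generator is the validation instrument: identical configurations are
byte-identical, planted relative reporting rates are recovered by the
pipeline's ROR within its confidence interval, an all-null panel keeps the
four-method positive rate below 1%, and planted Weibull parameters are
recovered by the fitter. `make_funnel_fixture()` is a deterministic
50,000-case database with 500 drugs of which 71 carry strong planted
signals (RR 25) and 7 of those sit on the bundled exclusion list, so the
end-to-end funnel runs 71 positives down to 64 — the arithmetic shape of a
published alopecia signal screen.

What the synthetic data does *not* emulate: free-text drug-name noise,
correlated event backgrounds (background PTs are drawn independently),
reporting-rate drift within a drug over calendar time, and true
polypharmacy confounding (concomitant drugs are independent of the event).
Passing tests therefore demonstrate the correctness of the statistical
machinery under the stated generative model, not robustness to every
artefact of real spontaneous-report data.

## Validation problem sizes and numerical choices

The packaged validation uses sizes chosen to make the Monte-Carlo noise
small relative to the asserted margins while keeping a full run
desk-scale: the null calibration uses 200 drugs over 100,000 cases; the
detection/coverage study uses 100 replicates of 50,000 cases with a
planted RR of 10 at a base rate of 0.004 (a rarer event than the default
so that the odds ratio tracks the rate ratio to within ~4%); MGPS
recovery uses 5,000 simulated pairs; Weibull recovery uses 200 replicates
of n = 500 at shapes 0.5, 1 and 2. Fisher's exact test is verified against
full hypergeometric enumeration over every margin configuration with
N <= 40 (reduced to canonical margins by the row/column-swap invariance of
the conditional test).

Numerical notes: contingency cells are held as doubles in all formulas
(cell products overflow 32-bit integers at FAERS scale); the MGPS
marginal likelihood is evaluated with a log-sum-exp and the optimizer is
boxed away from overflow; EBGM05 root-finding brackets the quantile using
gamma quantiles of the mixture components. For EBGM recovery, pairs with
`a = 0` under a heavy-tailed prior have EBGMs near machine zero, where
relative error is not meaningful; recovery there is judged on the mean.

## Known limitations

Disproportionality quantifies reporting, not incidence: no causal or
rate interpretation is licensed. Legacy (pre-2012, ISR-keyed) FAERS files
are not supported — only `primaryid`-keyed tables. The per-drug statistics
printed by large published screens are generally not reproducible without
the authors' exact extract and cleaning choices; this package's published
reference tables are used for arithmetic consistency checks (shares,
tiers, cross-tabs), never as fitting targets.
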