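---
title: "Disproportionality signal detection for spontaneous-report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdp)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect reports
that each link a patient, one or more drugs, and one or more adverse events
coded as MedDRA preferred terms (PTs). Because there is no denominator of
exposed patients, risk cannot be estimated; what can be estimated is
*disproportionality* — whether an event is reported more often with a given
drug than the rest of the database would predict. `faersdp` implements the
standard pipeline around that idea for a single drug–indication cohort
(the motivating case is ustekinumab prescribed for Crohn's disease):
ingestion of FAERS-style quarterly files, deduplication, cohort extraction,
2×2 table construction at PT and system-organ-class (SOC) level, four
disproportionality statistics with a combined signal criterion, and the
descriptive tables a pharmacovigilance report is built from. A synthetic
generator with planted signals closes the loop, so every stage is validated
against known ground truth rather than against an unavailable extract.

## From reports to 2×2 tables

A *case* may be submitted repeatedly as new versions. Deduplication keeps
the highest `caseversion` per `caseid` (ties: latest receipt date, then
input order), then collapses reports with *distinct* case ids but identical
content on (sex, age, country, drug-name set, PT set, event-date set),
keeping the earliest received. The content rule is exact-match by design:
the verification fields one would fuzzily compare are not standardized
across submitters, and an exact rule is deterministic, idempotent and
testable. Both removal counts are reported.

The cohort is defined by *suspect* role only: a report joins the cohort when
the target drug appears as a suspect drug with one of the target indication
PTs, and its FDA receipt date falls in the analysis window (quarters,
`2016Q4`–`2023Q4` by default). Every other in-window report — including
target-drug reports for other indications — forms the background. Receipt
dates with only a year are kept when the whole year lies inside the window,
and excluded otherwise.

For each event the four-grid table counts distinct (report, event) pairs:

|            | event | no event |
|------------|-------|----------|
| cohort     | a     | b        |
| background | c     | d        |

with `N = a+b+c+d` and expected count `E = (a+b)(a+c)/N`. A report
mentioning the same PT twice counts once, and at SOC level a report counts
once per distinct SOC among its PTs. Tables are kept for every event with
`a ≥ 1`; the `a ≥ 3` gate belongs to signal evaluation, not to counting, so
descriptive outputs stay complete. Tables are crude (unstratified), which
matches routine practice for a single-indication cohort.

## The four statistics

**ROR** (reporting odds ratio): `(a·d)/(b·c)` with the Woolf interval
`exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.

**PRR** (proportional reporting ratio): `[a/(a+b)]/[c/(c+d)]` with
`exp(log PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`.

Zero cells make these undefined; `faersdp` returns `NA` and fails the
corresponding flag rather than applying a continuity correction, because a
silent +0.5 changes rankings and the `a ≥ 3` gate already removes the cells
a correction would rescue.

**BCPNN IC**: the shrinkage observed-to-expected information component
`IC = log2((a+0.5)/(E+0.5))`, with the closed-form lower credibility bound
`IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`. The added 0.5 is a
prior pulling small-count cells toward IC = 0, so the statistic is defined
for every table. This closed form is the posterior summary of the model
`a ~ Poisson(λE)` with `λ ~ Gamma(0.5, 0.5)`, whose posterior is
`λ ~ Gamma(a+0.5, E+0.5)`. The package therefore ships `mc_ic_oracle()`, a
posterior-simulation route through exactly that gamma posterior, as the
independent validation of the closed form: the closed-form IC is the log of
the posterior mean while the Monte-Carlo mean averages the log, so the two
agree up to a Jensen gap that is below 0.15 at `a = 10` and vanishes as
counts grow — which is what the oracle tests assert. (The original 1998
fully Bayesian BCPNN with Beta posteriors for the three marginal
probabilities is a *different* estimator: at small expected counts it can
sit several tenths of an IC unit away from the shrinkage closed form, so it
cannot serve as a tight oracle for it.)

**MGPS EBGM**: the empirical-Bayes gamma-Poisson shrinker. All cells share
the prior `λ ~ w·Gamma(α₁,β₁) + (1−w)·Gamma(α₂,β₂)`; integrating the
Poisson likelihood gives a two-component negative-binomial marginal whose
summed log-likelihood `fit_mgps_prior()` maximizes over
`(log α₁, log β₁, log α₂, log β₂, logit w)` — Nelder-Mead from the
canonical start `(0.2, 0.1, 2, 4, 1/3)` plus four seeded random restarts,
BFGS polish of the best. The posterior for a cell is again a gamma mixture,
`Gamma(αⱼ+a, βⱼ+E)` with data-updated weights, and

* `EBGM = 2^{E[log2 λ | a]}`, via the digamma closed form
  `E[log λ] = Σⱼ Qⱼ(ψ(αⱼ+a) − log(βⱼ+E))`;
* `EBGM05` = the lower posterior percentile, found by monotone root-finding
  on the mixture CDF between the two component quantiles, to relative
  tolerance 1e−8 (bracket widened geometrically if floating point puts the
  CDF on the wrong side of an endpoint).

`EBGM05` defaults to the **5th** percentile — the MGPS convention — with
`percentile = 0.025` available, since published table headers sometimes
describe the same column as a 95% interval bound. The threshold
(`EBGM05 > 2`) is conventionally stated against EB05, which is why the 5th
is the default.

## Signal criterion

A PT is a signal when **all four** methods fire on full-precision values:
`a ≥ 3 ∧ ROR ≥ 3 ∧ ROR_lo > 1`; `a ≥ 3 ∧ PRR ≥ 2 ∧ PRR_lo > 1`;
`IC025 > 0`; `EBGM05 > 2`. The inequalities are implemented exactly as
stated, including the point-estimate requirement `ROR ≥ 3` (stricter than
the common `lo > 1`-only rule). Non-computable statistics fail their flag.
Rankings (by report count or by ROR) break ties by the other key, then by
event name, so output order is total and reproducible.

## Descriptive outputs

Percentages are rounded to two decimals. Denominators are explicit because
they differ by block and cannot be guessed from the output: demographic
blocks (sex, age bands, reporter, country, route, year) use the cohort
size; the outcome block uses the number of outcome *entries* (a report can
carry several codes); the time-to-onset block uses the number of reports
with a therapy record for the target drug, including those whose dates do
not yield a usable onset time. Each block records its denominator in an
attribute and the pipeline writes it into the table headers.

Time to onset is `earliest event date − earliest therapy start` of the
target drug, in whole days, binned into `[0,7)`, `[7,28)`, `[28,60)`,
`[60,∞)`. Published bin labels like "7–28" and "28–60" overlap at the
boundary, so a convention is required: bins are half-open and
lower-inclusive (day 7 → "7–28", day 28 → "28–60"). Negative onsets (event
before therapy) and partial dates are "unspecified". Medians and quartiles
use linear interpolation between order statistics (R's default type 7);
the convention is pinned because reproducibility at two decimals depends
on it.

Death proportion per SOC divides reports whose outcomes include the death
code `DE` by all cohort reports with at least one PT in that SOC; a report
contributes to every SOC it touches.

## The synthetic generator

`generate_reports()` emulates the statistical structure the pipeline
assumes: case ids with duplicate versions, suspect-drug and indication
fields, one-to-many report→PT structure, demographics with "unspecified"
missingness, outcome codes including death, and therapy/event dates for
time to onset. Each report's PT set is per-PT Bernoulli at the catalog's
background rate, multiplied by the planted rate ratio for planted PTs in
cohort reports; empty PT sets are redrawn, mirroring the ingestion
invariant that a report carries at least one reaction (this conditioning
inflates marginal rates by the factor `1/(1−P(empty))`, which the
frequency-convergence test accounts for). Each field group draws from its
own RNG stream derived from the master seed, so adding a field to one
group never perturbs another group's draws and fixtures stay stable.

Defaults are the package's benchmark conditions: 5,000 cohort and 100,000
background cases, ~1.7 events per report across 61 PTs in 20 SOCs, 5%
duplicate versions, missingness near what spontaneous-report data shows
(sex ~7%, age ~37%, onset dates ~35%), a log-normal time-to-onset around
60 days with heavy spread, and per-SOC death rates between 0.6% and 7.5%.
About 3% of background cases carry the target drug for a different
indication, exercising the indication filter. What the generator does
*not* model: reporting biases of real systems (stimulated reporting, the
Weber effect), correlated PT co-occurrence, drug interactions, or secular
trends — so passing benchmarks demonstrate correctness of the machinery
and calibration under the stated model, not performance on real FAERS
extracts.

## Validation problem sizes

The test suite validates the MGPS fit on 20,000 cells drawn from the known
prior `(0.2, 0.1, 2, 4, 1/3)` (the fitted likelihood must reach the true
parameters' likelihood) and on 5,000 null cells (`λ ≡ 1`; fitted prior
mean within 20% of 1). Pipeline operating characteristics use one
full-size planted run (tenfold elevation of a 1%-background PT; the
combined criterion must detect it) and twenty null databases of 2,000 +
40,000 reports each, pooling the false-positive rate of the quadruple
criterion among PTs with `a ≥ 3`, which stays below 1% — the quadruple
criterion is deliberately conservative.

## Known limitations

* The bundled PT→SOC dictionary is a small open stand-in; the licensed
  MedDRA terminology must be supplied by the user as a `pt,soc` table for
  real analyses. Unmapped PTs surface as `UNMAPPED` rather than being
  dropped.
* Drug-name standardization is a static synonym table, not an NLP engine;
  unmatched verbatim strings pass through unchanged and are logged.
* Tables are crude; there is no age/sex/year stratification of expected
  counts and no multiplicity adjustment, matching routine single-cohort
  practice.
* With few events (tens of cells) the five-parameter mixture prior is
  weakly identified; the fit is still deterministic and the resulting EBGM
  is well-behaved, but fitted hyperparameters should not be interpreted.
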