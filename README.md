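# faersdp

Disproportionality signal detection for FAERS-style spontaneous
adverse-event report data.

Spontaneous-report databases have no exposure denominator, so drug safety
signals are found by *disproportionality*: for each drug–event pair, the
2×2 table

|            | event | no event |
|------------|------:|---------:|
| cohort     | a     | b        |
| background | c     | d        |

is summarized by four statistics — the reporting odds ratio
`ROR = ad/bc`, the proportional reporting ratio
`PRR = [a/(a+b)]/[c/(c+d)]` (both with log-scale 95% intervals), the BCPNN
information component `IC = log2((a+0.5)/(E+0.5))` with
`E = (a+b)(a+c)/N` and its lower credibility bound IC025, and the MGPS
empirical-Bayes geometric mean `EBGM` with its lower posterior percentile
EBGM05, obtained from a two-component gamma-mixture prior fitted to all
cells by maximum marginal likelihood. A pair is a **signal** when all four
fire: `a ≥ 3 ∧ ROR ≥ 3 ∧ ROR_lo > 1`, `a ≥ 3 ∧ PRR ≥ 2 ∧ PRR_lo > 1`,
`IC025 > 0`, `EBGM05 > 2`.

The package covers the full pipeline for a single drug–indication cohort
(the motivating case is ustekinumab in Crohn's disease): parsing FAERS
quarterly `$`-delimited files or a compact normalized-csv dialect,
drug-name standardization via a synonym table, case deduplication, cohort
extraction by suspect role + indication + receipt window, PT- and SOC-level
contingency tables, the four statistics, combined-criterion signal lists,
and descriptive tables (demographics, time to onset, reports per year,
death proportion per system organ class). A synthetic report-database
generator with planted signals makes every stage testable against known
ground truth; it is first-class, tested code, not a fixture.

It is aimed at pharmacovigilance analysts and methods researchers who want
a transparent, reproducible re-implementation of the routine
disproportionality stack with its numerical choices documented and tested.

## Worked example

The numbered scripts under `analysis/` run the study end to end on a
simulated database (5,000 cohort + 100,000 background cases, one planted
tenfold elevation of "Abscess" in the cohort):

```sh
Rscript analysis/01_simulate.R      # write the database + ground truth
Rscript analysis/02_ingest_dedup.R  # ingest, standardize, dedup, cohort split
Rscript analysis/03_signals.R       # tables, prior fit, statistics, signals
Rscript analysis/04_descriptives.R  # table1/table4/yearly
Rscript analysis/05_benchmark.R     # sensitivity + null false-positive rate
```

Step 2 prints the filter flow — every step's count is written to
`results/counts.csv`:

```
         step      n
    extracted 110357
 deduplicated 103134
    in_window 103134
       cohort   4930
version duplicates removed: 5357 ; cross-id duplicates removed: 1866
```

and step 3 recovers exactly the planted signal:

```
1 of 61 PTs meet all four criteria
   event n_reports  ror ic025 ebgm05
 Abscess       613 10.7  2.61   6.72
```

i.e. 613 of 4,930 cohort reports mention the planted PT, its reporting
odds are ~10.7 times the background odds (matching the planted rate ratio
of 10), the IC lower bound is well above 0 and the EBGM lower percentile
well above 2 — while none of the 60 unelevated PTs crosses the combined
criterion.

The same machinery is available programmatically:

```r
library(faersdp)
ror(10, 90, 100, 9900)
#> # A tibble: 1 x 3
#>     est    lo    hi
#>   <dbl> <dbl> <dbl>
#> 1    11  5.56  21.8
ic_bcpnn(10, 90, 100, 9900)
#> # A tibble: 1 x 2
#>      ic ic025
#>   <dbl> <dbl>
#> 1  2.72  1.65
```

`run_pipeline()` drives the whole flow from a single declarative YAML
config (see `inst/extdata/demo_config.yaml`); rerunning a config produces
byte-identical CSVs.

## On-disk formats

* **FAERS ASCII**: `$`-delimited `DEMO/DRUG/REAC/INDI/OUTC/THER` with the
  standard column names (`primaryid`, `caseid`, `caseversion`, `fda_dt`,
  `drugname`, `role_cod`, `indi_pt`, `start_dt`, `pt`, `event_dt`,
  `outc_cod`, ...). Dates may be partial (`YYYY`, `YYYYMM`, `YYYYMMDD`).
* **normalized-csv**: the package's three-file dialect — `reports.csv`
  (one row per report; outcome codes `;`-separated), `drugs.csv` and
  `reactions.csv` (long). This dialect round-trips a `faers_data` object
  exactly.
* **Dictionaries**: a PT→SOC table as `pt,soc` CSV (the bundled
  `meddra_toy.csv` is a small open stand-in for the licensed MedDRA
  terminology) and a drug synonym table as `raw,canonical` CSV.

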