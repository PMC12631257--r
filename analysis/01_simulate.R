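#!/usr/bin/env Rscript
# Step 1: simulate the benchmark report database.
#
# Builds a FAERS-like spontaneous-report database at the study's benchmark
# conditions — 5,000 cohort cases (ustekinumab, Crohn's disease) against
# 100,000 background cases, 5% duplicate case versions — with one planted
# signal: a tenfold reporting-rate elevation of "Abscess" in the cohort.
# The database is written in the normalized-csv dialect together with the
# ground truth, so the later steps can run from disk exactly as they would
# on a real FAERS extract.

library(faersdp)

out_dir <- "results/sim"
cfg <- synth_config(planted = data.frame(pt = "Abscess", rate_ratio = 10),
                    seed = 20260101)
gen <- generate_reports(cfg)

write_reports(gen$reports, out_dir, dialect = "normalized-csv")
readr::write_csv(gen$truth, file.path(out_dir, "truth.csv"))

cat("simulated", n_reports(gen$reports), "reports (",
    length(unique(gen$reports$demo$caseid)), "cases ) ->", out_dir, "\n")
cat("planted:", paste(gen$truth$pt, "x", gen$truth$rate_ratio), "\n")
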