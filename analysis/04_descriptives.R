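#!/usr/bin/env Rscript
# Step 4: descriptive tables for the cohort.
#
# Demographic composition, time to onset, reports per year, and the death
# proportion per system organ class, in the shape of the standard
# pharmacovigilance summary tables.

library(faersdp)

cohort <- read_reports("results/cohort", dialect = "normalized-csv")
dict <- meddra_dictionary(system.file("extdata", "meddra_toy.csv",
                                      package = "faersdp"))

dem <- summarize_demographics(cohort, "ustekinumab")
tto <- summarize_tto(cohort, "ustekinumab")
table1 <- dplyr::bind_rows(c(
  lapply(dem[c("sex", "age_band", "reporter", "country", "route",
               "outcomes", "year")],
         function(b) tibble::tibble(level = as.character(b$level),
                                    n = b$n, pct = b$pct)),
  list(tto = tibble::tibble(level = tto$bins$level, n = tto$bins$n,
                            pct = tto$bins$pct))), .id = "block")
table4 <- death_proportion_by_soc(cohort, dict)

readr::write_csv(table1, "results/table1.csv")
readr::write_csv(table4, "results/table4.csv")
readr::write_csv(yearly_counts(cohort), "results/yearly.csv")

cat("cohort size:", n_reports(cohort), "\n")
cat(sprintf("age median (IQR): %g (%g-%g)\n",
            dem$age$median, dem$age$q1, dem$age$q3))
cat(sprintf("TTO median (IQR): %g (%g-%g) days over %d reports\n",
            tto$summary$median, tto$summary$q1, tto$summary$q3,
            attr(tto$bins, "denominator")))
cat("death proportion by SOC (top 5):\n")
print(as.data.frame(utils::tail(table4, 5)), row.names = FALSE)
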