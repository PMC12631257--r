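test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_cohort = 120, n_background = 600, seed = 21,
                      planted = data.frame(pt = "Abscess", rate_ratio = 5))
  g1 <- generate_reports(cfg)
  g2 <- generate_reports(cfg)
  for (tab in c("demo", "drugs", "reactions", "outcomes")) {
    expect_identical(g1$reports[[tab]], g2$reports[[tab]], info = tab)
  }
  expect_identical(g1$truth, g2$truth)
  # and a different seed changes the draw
  g3 <- generate_reports(synth_config(n_cohort = 120, n_background = 600,
                                      seed = 22))
  expect_false(identical(g1$reports$reactions, g3$reports$reactions))
})

test_that("duplicate cases are emitted at the configured rate and collapse back", {
  cfg <- synth_config(n_cohort = 200, n_background = 800, seed = 31,
                      duplicate_rate = 0.2)
  g <- generate_reports(cfg)
  n_emitted <- n_reports(g$reports)
  expect_gt(n_emitted, 1000 + 0.2 * 1000 * 0.6)   # within sampling range
  expect_lt(n_emitted, 1000 + 0.2 * 1000 * 1.4)
  expect_equal(max(g$reports$demo$caseversion), 2L)
  dd <- deduplicate(g$reports)
  # version duplicates collapse exactly; identical-content singles may also
  # merge under the cross-id rule, so at most 1000 cases remain
  expect_equal(attr(dd, "removed_version"), n_emitted - 1000L)
  expect_lte(n_reports(dd), 1000L)
})

test_that("generated databases round-trip through both on-disk dialects", {
  cfg <- synth_config(n_cohort = 60, n_background = 200, seed = 41)
  fd <- generate_reports(cfg)$reports
  dir_csv <- withr::local_tempdir()
  write_reports(fd, dir_csv, "normalized-csv")
  back_csv <- read_reports(dir_csv, "normalized-csv")
  for (tab in c("demo", "drugs", "reactions", "outcomes")) {
    expect_equal(as.data.frame(back_csv[[tab]]), as.data.frame(fd[[tab]]),
                 info = paste("csv", tab))
  }
  dir_ascii <- withr::local_tempdir()
  write_reports(fd, dir_ascii, "faers-ascii")
  back_ascii <- read_reports(dir_ascii, "faers-ascii")
  expect_equal(n_reports(back_ascii), n_reports(fd))
  expect_equal(back_ascii$reactions$pt, fd$reactions$pt)
  expect_equal(back_ascii$drugs$indication_pt, fd$drugs$indication_pt)
})

test_that("background PT frequencies converge to the configured rates", {
  cfg <- synth_config(n_cohort = 100, n_background = 20000, seed = 51,
                      duplicate_rate = 0)
  fd <- generate_reports(cfg)$reports
  bg_ids <- fd$demo$primaryid[-(1:100)]
  bg <- fd$reactions[fd$reactions$primaryid %in% bg_ids, ]
  n_bg <- length(bg_ids)
  for (pt in c("Off label use", "Diarrhoea", "Abscess")) {
    p <- cfg$pt_catalog$background_rate[cfg$pt_catalog$pt == pt]
    # empty-set resampling inflates marginal rates slightly; allow for it
    p_eff <- p / (1 - prod(1 - cfg$pt_catalog$background_rate))
    obs <- sum(bg$pt == pt) / n_bg
    se <- sqrt(p_eff * (1 - p_eff) / n_bg)
    expect_lt(abs(obs - p), 3 * se + (p_eff - p), label = pt)
  }
})

test_that("a planted rate ratio of 10 shows up in the empirical ROR", {
  cfg <- synth_config(n_cohort = 2000, n_background = 20000, seed = 61,
                      duplicate_rate = 0,
                      planted = data.frame(pt = "Abscess", rate_ratio = 10))
  fd <- generate_reports(cfg)$reports
  sp <- filter_cohort(fd, "ustekinumab", "Crohn's disease", c("2016Q4", "2023Q4"))
  tab <- build_tables(sp$cohort, sp$background, "pt")
  x <- tab[tab$event == "Abscess", ]
  r <- ror(x$a, x$b, x$c, x$d)
  expect_gt(r$est, 6)
  expect_lt(r$est, 16)
})

test_that("invalid configurations fail fast naming the offending field", {
  expect_error(synth_config(n_cohort = 0), "n_cohort")
  expect_error(synth_config(duplicate_rate = 1.2), "duplicate_rate")
  expect_error(synth_config(planted = data.frame(pt = "Nope", rate_ratio = 2)),
               "planted")
  expect_error(synth_config(planted = data.frame(pt = "Off label use",
                                                 rate_ratio = 50)),
               "rate_ratio")
  expect_error(synth_config(missing_rates = list(sex = 2, age = 0, country = 0,
                                                 event_date = 0,
                                                 therapy_start = 0)),
               "missing_rates")
})

test_that("recovery reports NA sensitivity when nothing is planted", {
  cfg <- synth_config(n_cohort = 150, n_background = 1500, seed = 71)
  rec <- suppressMessages(end_to_end_recovery(cfg))
  expect_true(is.na(rec$sensitivity))
  expect_gte(rec$false_positive_rate, 0)
  # pipeline counts shrink monotonically
  expect_lte(rec$counts$deduplicated, rec$counts$generated)
  expect_lte(rec$counts$cohort, rec$counts$deduplicated)
})
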