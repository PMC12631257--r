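test_that("partial FAERS dates parse to usable years and full dates to Date", {
  expect_equal(faers_date(c("20200321", "202003", "2020", "", "2020133x")),
               as.Date(c("2020-03-21", NA, NA, NA, NA)))
  # a junk month/day part still carries a usable year, but no calendar date
  expect_equal(faers_year(c("20200321", "202003", "2020", "", "20201332")),
               c(2020L, 2020L, 2020L, NA, 2020L))
  expect_true(is.na(faers_date("20201332")))
  expect_equal(parse_quarter(c("2016Q4", "2023Q4")), c(8068L, 8096L))
  expect_error(parse_quarter("2016-13"), "invalid quarter")
  expect_equal(date_quarter(as.Date("2016-10-01")), parse_quarter("2016Q4"))
})

test_that("a six-report FAERS ASCII fixture round-trips with linked tables", {
  fd <- six_reports()
  dir <- withr::local_tempdir()
  write_reports(fd, dir, dialect = "faers-ascii")
  back <- read_reports(dir, dialect = "faers-ascii")
  expect_equal(n_reports(back), 6)
  expect_equal(back$demo$caseid, fd$demo$caseid)
  expect_equal(nrow(back$reactions), nrow(fd$reactions))
  expect_equal(back$reactions$pt, fd$reactions$pt)
  # drug linkage: indication and therapy start survive the INDI/THER joins
  d1 <- back$drugs[back$drugs$primaryid == "1000011", ]
  expect_equal(d1$indication_pt, "Crohn's disease")
  expect_equal(d1$therapy_start, as.Date("2020-01-01"))
  expect_equal(sort(back$outcomes$outcome[back$outcomes$primaryid == "1000011"]),
               c("DE", "HO"))
  expect_equal(back$demo$sex, fd$demo$sex)
  expect_equal(back$demo$age_years, fd$demo$age_years)
})

test_that("normalized-csv dialect round-trips a database exactly", {
  fd <- six_reports()
  dir <- withr::local_tempdir()
  write_reports(fd, dir, dialect = "normalized-csv")
  back <- read_reports(dir, dialect = "normalized-csv")
  for (tab in c("demo", "drugs", "reactions", "outcomes")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(fd[[tab]]),
                 info = tab)
  }
})

test_that("missing mandatory files are hard errors naming the file", {
  dir <- withr::local_tempdir()
  write_reports(six_reports(), dir, dialect = "faers-ascii")
  file.remove(file.path(dir, "REAC.txt"))
  expect_error(read_reports(dir, dialect = "faers-ascii"), "REAC")
  dir2 <- withr::local_tempdir()
  write_reports(six_reports(), dir2, dialect = "faers-ascii")
  file.remove(file.path(dir2, "DEMO.txt"))
  expect_error(read_reports(dir2, dialect = "faers-ascii"), "DEMO")
})

test_that("an empty REAC table and malformed headers are rejected", {
  dir <- withr::local_tempdir()
  write_reports(six_reports(), dir, dialect = "faers-ascii")
  writeLines("primaryid$pt$event_dt", file.path(dir, "REAC.txt"))
  expect_error(read_reports(dir, dialect = "faers-ascii"), "REAC")
  # comma-delimited header in a $-delimited file
  writeLines(c("primaryid,pt", "1,Abscess"), file.path(dir, "REAC.txt"))
  expect_error(read_reports(dir, dialect = "faers-ascii"), "line 1")
})

test_that("reports without reactions are dropped with a logged count", {
  fd <- six_reports()
  dir <- withr::local_tempdir()
  write_reports(fd, dir, dialect = "faers-ascii")
  # append a DEMO row with no reactions
  cat("9999991$9999991$1$20200101$F$40$YR$US$MD\n",
      file = file.path(dir, "DEMO.txt"), append = TRUE)
  expect_message(back <- read_reports(dir, dialect = "faers-ascii"),
                 "1 report\\(s\\) without reactions")
  expect_equal(n_reports(back), 6)
  expect_equal(attr(back, "dropped_no_reaction"), 1L)
})

test_that("drug names standardize through the synonym table and pass through otherwise", {
  fd <- six_reports()
  expect_true("STELARA" %in% fd$drugs$drug_name)
  std <- suppressMessages(standardize_drug_names(fd, toy_synonyms()))
  expect_false("STELARA" %in% std$drugs$drug_name)
  expect_equal(sum(std$drugs$drug_name == "ustekinumab"), 5)
  # idempotent on canonical names; unknown strings untouched
  fd2 <- bind_reports(mk_report("77777771", drug = "XYZ123"))
  expect_message(std2 <- standardize_drug_names(fd2, toy_synonyms()), "XYZ123")
  expect_equal(std2$drugs$drug_name, "XYZ123")
  std3 <- suppressMessages(standardize_drug_names(std, toy_synonyms()))
  expect_equal(std3$drugs$drug_name, std$drugs$drug_name)
})

test_that("PT to SOC mapping is case-insensitive with an UNMAPPED sentinel", {
  dict <- toy_dict()
  expect_equal(map_pt_to_soc(dict, "Abscess"), "Infections and infestations")
  expect_equal(map_pt_to_soc(dict, "  myocardial   infarction "),
               "Cardiac disorders")
  expect_message(soc <- map_pt_to_soc(dict, "Qqqq"), "UNMAPPED")
  expect_equal(soc, "UNMAPPED")
  expect_error(meddra_dictionary(data.frame(pt = c("A", "a"), soc = c("X", "Y"))),
               "exactly one SOC")
})
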