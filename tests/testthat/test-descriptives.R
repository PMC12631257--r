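test_that("category percentages use the cohort denominator at 2 decimals", {
  # 7 female of 12 reports -> 58.33%
  reps <- c(lapply(1:7, function(i) mk_report(sprintf("F%02d1", i))),
            lapply(1:5, function(i) mk_report(sprintf("M%02d1", i), sex = "male")))
  fd <- do.call(bind_reports, reps)
  dem <- summarize_demographics(fd, "ustekinumab")
  expect_equal(dem$sex$n[dem$sex$level == "female"], 7L)
  expect_equal(dem$sex$pct[dem$sex$level == "female"], 58.33)
  expect_equal(sum(dem$sex$pct), 100, tolerance = 0.05)
  expect_equal(sum(dem$age_band$n), 12L)
})

test_that("all-missing sex collapses to a single unspecified category", {
  fd <- do.call(bind_reports,
                lapply(1:4, function(i) mk_report(sprintf("U%02d1", i),
                                                  sex = "unspecified")))
  dem <- summarize_demographics(fd)
  expect_equal(dem$sex$pct[dem$sex$level == "unspecified"], 100)
})

test_that("age median and IQR use linear interpolation between order statistics", {
  fd <- bind_reports(mk_report("A011", age = 31), mk_report("A021", age = 45),
                     mk_report("A031", age = 59))
  dem <- summarize_demographics(fd)
  expect_equal(dem$age$median, 45)
  expect_equal(dem$age$q1, 38)
  expect_equal(dem$age$q3, 52)
})

test_that("time to onset is event minus therapy start with half-open bins", {
  fd <- bind_reports(
    mk_report("T011", therapy_start = "2020-01-01", event_dates = "2020-03-21"),
    mk_report("T021", therapy_start = "2020-01-01", event_dates = "2020-01-08"),
    mk_report("T031", therapy_start = "2020-01-10", event_dates = "2020-01-05"),
    mk_report("T041", therapy_start = NA, event_dates = "2020-01-05")
  )
  tto <- compute_tto(fd, "ustekinumab")
  expect_equal(tto$tto_days[tto$primaryid == "T011"], 80L)
  expect_equal(tto$bin[tto$primaryid == "T011"], ">=60")
  expect_equal(tto$tto_days[tto$primaryid == "T021"], 7L)
  expect_equal(tto$bin[tto$primaryid == "T021"], "7-28")  # day 7 is in [7,28)
  expect_equal(tto$bin[tto$primaryid == "T031"], "unspecified")  # negative
  expect_equal(tto$bin[tto$primaryid == "T041"], "unspecified")  # missing start
})

test_that("bin labels stay consistent with day counts over random dates", {
  set.seed(88)
  days <- sample(c(NA, 0:400), 300, replace = TRUE)
  fd <- do.call(bind_reports, lapply(seq_along(days), function(i) {
    start <- as.Date("2020-01-01")
    mk_report(sprintf("R%04d1", i), therapy_start = "2020-01-01",
              event_dates = if (is.na(days[i])) NA
                            else format(start + days[i]))
  }))
  tto <- compute_tto(fd, "ustekinumab")
  ref <- function(d) {
    if (is.na(d) || d < 0) "unspecified"
    else if (d < 7) "<7" else if (d < 28) "7-28"
    else if (d < 60) "28-60" else ">=60"
  }
  expect_equal(tto$bin, vapply(tto$tto_days, ref, ""))
  expect_equal(sort(unique(tto$bin[!is.na(tto$tto_days)])),
               sort(setdiff(unique(vapply(days, ref, "")), "unspecified")))
})

test_that("death proportions per SOC match direct arithmetic", {
  # 24 deaths of 320 cardiac reports -> 7.50; 8 of 357 hepatobiliary -> 2.24
  mk_soc_block <- function(prefix, n, deaths, pt) {
    lapply(seq_len(n), function(i)
      mk_report(paste0(prefix, i, "1"), pts = pt,
                outcomes = if (i <= deaths) "DE" else character(0)))
  }
  fd <- do.call(bind_reports, c(
    mk_soc_block("CARD", 320, 24, "Myocardial infarction"),
    mk_soc_block("HEPA", 357, 8, "Cholangitis")
  ))
  t4 <- death_proportion_by_soc(fd, toy_dict())
  card <- t4[t4$soc == "Cardiac disorders", ]
  expect_equal(c(card$deaths, card$total), c(24, 320))
  expect_equal(card$proportion, 7.50)
  hepa <- t4[t4$soc == "Hepatobiliary disorders", ]
  expect_equal(hepa$proportion, 2.24)
  expect_true(all(t4$deaths <= t4$total))
  expect_true(all(t4$proportion >= 0 & t4$proportion <= 100))
})

test_that("a SOC with no deaths reports 0.00 and empty SOCs are omitted", {
  fd <- do.call(bind_reports,
                lapply(1:100, function(i) mk_report(sprintf("Z%03d1", i),
                                                    pts = "Headache")))
  t4 <- death_proportion_by_soc(fd, toy_dict())
  expect_equal(t4$soc, "Nervous system disorders")
  expect_equal(t4$proportion, 0)
})

test_that("yearly counts partition the cohort and percentages sum to 100", {
  fd <- do.call(bind_reports, c(
    lapply(1:3, function(i) mk_report(sprintf("Y1%02d1", i), receipt = "2019-05-01")),
    lapply(1:9, function(i) mk_report(sprintf("Y2%02d1", i), receipt = "2020-05-01"))
  ))
  yc <- yearly_counts(fd)
  expect_equal(yc$n, c(3L, 9L))
  expect_equal(yc$pct, c(25, 75))
  expect_equal(sum(yc$n), n_reports(fd))
  expect_equal(sum(yc$pct), 100, tolerance = 0.05)
})

test_that("TTO percentages are over the therapy-record block", {
  fd <- bind_reports(
    mk_report("W011", therapy_start = "2020-01-01", event_dates = "2020-01-03"),
    mk_report("W021", therapy_start = "2020-01-01", event_dates = NA),
    mk_report("W031", drug = "adalimumab", indication = "Rheumatoid arthritis")
  )
  s <- summarize_tto(fd, "ustekinumab")
  expect_equal(attr(s$bins, "denominator"), 2L)  # W031 has no target-drug record
  expect_equal(s$bins$pct[s$bins$level == "<7"], 50)
  expect_equal(s$bins$pct[s$bins$level == "unspecified"], 50)
})
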