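#' Demographic and reporting summaries of a cohort
#'
#' Category counts and percentages in the shape of a standard
#' pharmacovigilance "Table 1": sex, age bands (`<20`, decade bands to
#' `>=60`, `unspecified`), reporter type, reporting country, route of
#' administration of the target drug, outcome codes, and reporting year.
#' Percentages use the cohort size as denominator and are rounded to two
#' decimals, except the outcome block, whose denominator is the number of
#' outcome entries (one report can carry several outcome codes, and reports
#' without any carry none) — each block records its denominator in a
#' `denominator` attribute. The age summary uses the median and quartiles
#' with linear interpolation between order statistics.
#'
#' @param cohort a non-empty [faers_data] object.
#' @param drug canonical name of the target drug, used to pick the route
#'   rows; `NULL` summarizes routes over all suspect drugs.
#' @return a named list of tibbles (`sex`, `age_band`, `age`, `reporter`,
#'   `country`, `route`, `outcomes`, `year`), each with columns
#'   `level`, `n`, `pct`.
#' @export
summarize_demographics <- function(cohort, drug = NULL) {
  stopifnot(inherits(cohort, "faers_data"))
  n <- n_reports(cohort)
  assert_that(n > 0, "cohort is empty")
  demo <- cohort$demo

  block <- function(x, levels, denom = n) {
    x <- factor(x, levels = levels)
    tab <- tibble::tibble(level = levels,
                          n = as.integer(table(x)[levels]))
    tab$pct <- pct2(tab$n, denom)
    attr(tab, "denominator") <- denom
    tab
  }

  sex <- block(demo$sex, c("female", "male", "unspecified"))

  age_band <- cut(demo$age_years,
                  breaks = c(-Inf, 20, 30, 40, 50, 60, Inf), right = FALSE,
                  labels = c("<20", "20-29", "30-39", "40-49", "50-59", ">=60"))
  age_band <- as.character(age_band)
  age_band[is.na(age_band)] <- "unspecified"
  age_tab <- block(age_band, c("<20", "20-29", "30-39", "40-49", "50-59",
                               ">=60", "unspecified"))

  qa <- stats::quantile(demo$age_years, c(0.25, 0.5, 0.75), na.rm = TRUE,
                        type = 7, names = FALSE)
  age <- tibble::tibble(median = qa[2], q1 = qa[1], q3 = qa[3],
                        n_known = sum(!is.na(demo$age_years)))

  reporter <- block(demo$reporter,
                    c("consumer", "pharmacist", "physician",
                      "other-health-professional", "unspecified"))

  ctry <- demo$country
  ctry[is.na(ctry)] <- "unspecified"
  country <- dplyr::count(tibble::tibble(level = ctry), .data$level,
                          name = "n", sort = TRUE)
  country$pct <- pct2(country$n, n)
  attr(country, "denominator") <- n

  drg <- cohort$drugs[cohort$drugs$role == "suspect", ]
  if (!is.null(drug)) drg <- drg[norm_key(drg$drug_name) == norm_key(drug), ]
  rt <- dplyr::distinct(drg, .data$primaryid, .data$route)
  rt$route[is.na(rt$route)] <- "unspecified"
  route <- dplyr::count(rt, level = .data$route, name = "n", sort = TRUE)
  route$pct <- pct2(route$n, n)
  attr(route, "denominator") <- n

  oc <- cohort$outcomes
  outcomes <- dplyr::count(oc, level = .data$outcome, name = "n", sort = TRUE)
  outcomes$pct <- pct2(outcomes$n, max(nrow(oc), 1L))
  attr(outcomes, "denominator") <- nrow(oc)

  year <- yearly_counts(cohort)
  year <- tibble::tibble(level = as.character(year$year), n = year$n,
                         pct = year$pct)
  attr(year, "denominator") <- n

  list(sex = sex, age_band = age_tab, age = age, reporter = reporter,
       country = country, route = route, outcomes = outcomes, year = year)
}

tto_bin_levels <- c("<7", "7-28", "28-60", ">=60", "unspecified")

bin_tto <- function(days) {
  out <- rep("unspecified", length(days))
  ok <- !is.na(days) & days >= 0
  out[ok] <- as.character(cut(days[ok], breaks = c(0, 7, 28, 60, Inf),
                              right = FALSE,
                              labels = c("<7", "7-28", "28-60", ">=60")))
  out
}

#' Time to onset of the adverse event
#'
#' Days from the earliest therapy start of the target drug to the earliest
#' recorded event date, per report, binned into the conventional intervals
#' `[0,7)`, `[7,28)`, `[28,60)`, `[60,Inf)` (half-open, lower-inclusive, so
#' day 7 falls in `"7-28"` and day 28 in `"28-60"`). Missing either date, or
#' an event recorded before therapy start, yields bin `"unspecified"`.
#' Partially recorded dates (year only) are treated as missing.
#'
#' @param cohort a [faers_data] object.
#' @param drug canonical name of the target drug.
#' @return a tibble with one row per report that has a therapy record for
#'   the target drug: `primaryid`, `tto_days` (integer or `NA`), `bin`.
#' @export
compute_tto <- function(cohort, drug) {
  stopifnot(inherits(cohort, "faers_data"))
  drg <- cohort$drugs[norm_key(cohort$drugs$drug_name) == norm_key(drug), ]
  start <- dplyr::summarise(dplyr::group_by(drg, .data$primaryid),
                            start = suppressWarnings(min(.data$therapy_start,
                                                         na.rm = TRUE)))
  start$start[is.infinite(start$start)] <- NA
  evt <- dplyr::summarise(dplyr::group_by(cohort$reactions, .data$primaryid),
                          event = suppressWarnings(min(.data$event_date,
                                                       na.rm = TRUE)))
  evt$event[is.infinite(evt$event)] <- NA
  tto <- dplyr::left_join(start, evt, by = "primaryid")
  days <- as.integer(tto$event - tto$start)
  days[!is.na(days) & days < 0] <- NA
  tibble::tibble(primaryid = tto$primaryid, tto_days = days,
                 bin = bin_tto(days))
}

#' Summarize time to onset
#'
#' Median and interquartile range of the known onset times, and bin counts
#' with percentages. The percentage denominator is the number of reports in
#' the TTO block — those with a therapy record for the target drug —
#' including the `"unspecified"` bin, and is recorded in the `denominator`
#' attribute.
#'
#' @inheritParams compute_tto
#' @return a list with `summary` (median, q1, q3, n_known) and `bins`
#'   (level, n, pct).
#' @export
summarize_tto <- function(cohort, drug) {
  tto <- compute_tto(cohort, drug)
  qt <- stats::quantile(tto$tto_days, c(0.25, 0.5, 0.75), na.rm = TRUE,
                        type = 7, names = FALSE)
  bins <- tibble::tibble(
    level = tto_bin_levels,
    n = vapply(tto_bin_levels, function(b) sum(tto$bin == b), 0L,
               USE.NAMES = FALSE)
  )
  bins$pct <- pct2(bins$n, max(nrow(tto), 1L))
  attr(bins, "denominator") <- nrow(tto)
  list(summary = tibble::tibble(median = qt[2], q1 = qt[1], q3 = qt[3],
                                n_known = sum(!is.na(tto$tto_days))),
       bins = bins)
}

#' Death proportion by system organ class
#'
#' For each SOC: the number of cohort reports with at least one PT in that
#' SOC (`total`), the subset whose outcome codes include death (`DE`)
#' (`deaths`), and `proportion = 100 * deaths / total` rounded to two
#' decimals. A report with PTs in several SOCs contributes to each of them.
#' SOCs without any report are omitted.
#'
#' @param cohort a [faers_data] object with outcomes populated.
#' @param dictionary a [meddra_dictionary()].
#' @return a tibble `soc`, `deaths`, `total`, `proportion`, sorted by
#'   increasing proportion.
#' @export
death_proportion_by_soc <- function(cohort, dictionary) {
  stopifnot(inherits(cohort, "faers_data"))
  pairs <- dplyr::distinct(tibble::tibble(
    primaryid = cohort$reactions$primaryid,
    soc = map_pt_to_soc(dictionary, cohort$reactions$pt)))
  death_ids <- unique(cohort$outcomes$primaryid[cohort$outcomes$outcome == "DE"])
  pairs$death <- pairs$primaryid %in% death_ids
  out <- dplyr::summarise(dplyr::group_by(pairs, .data$soc),
                          deaths = sum(.data$death), total = dplyr::n())
  out$proportion <- pct2(out$deaths, out$total)
  out <- out[order(out$proportion, out$soc), ]
  tibble::as_tibble(out)
}

#' Reports per calendar year of receipt
#'
#' @param cohort a [faers_data] object.
#' @return a tibble `year`, `n`, `pct` (percent of the cohort, two
#'   decimals); years partition the cohort, so the counts sum to its size.
#' @export
yearly_counts <- function(cohort) {
  stopifnot(inherits(cohort, "faers_data"))
  yr <- cohort$demo$receipt_year
  out <- dplyr::count(tibble::tibble(year = yr), .data$year, name = "n")
  out <- out[order(out$year), ]
  out$pct <- pct2(out$n, n_reports(cohort))
  out
}
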