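#' Split a report database into drug-indication cohort and background
#'
#' Restricts to the analysis window (by FDA receipt quarter) and partitions
#' the in-window reports into the **cohort** — reports in which the target
#' drug appears as a *suspect* drug with one of the target indications — and
#' the **background** — every other in-window report, including target-drug
#' reports filed for other indications. Cohort and background are disjoint
#' and together exhaust the in-window reports.
#'
#' Reports whose receipt date is only partially recorded (year without a
#' calendar day) cannot be assigned to a quarter; they are kept when the
#' whole year lies inside the window and excluded otherwise.
#'
#' @param reports a deduplicated [faers_data] object.
#' @param drug canonical drug name (match is case- and
#'   whitespace-insensitive; run [standardize_drug_names()] first).
#' @param indication_pts character vector of indication preferred terms that
#'   define the cohort.
#' @param window length-2 character vector of quarters, e.g.
#'   `c("2016Q4", "2023Q4")`, both ends inclusive.
#' @return a list with elements `cohort` and `background`, both [faers_data]
#'   objects, plus `n_excluded_window` (reports outside the window).
#' @export
filter_cohort <- function(reports, drug, indication_pts,
                          window = c("2016Q4", "2023Q4")) {
  stopifnot(inherits(reports, "faers_data"))
  assert_that(length(window) == 2L, "window must be c(start, end)")
  w <- parse_quarter(window)
  assert_that(w[1] <= w[2], "window start quarter is after end quarter")

  demo <- reports$demo
  q <- rep(NA_integer_, nrow(demo))
  full <- !is.na(demo$receipt_date)
  q[full] <- date_quarter(demo$receipt_date[full])
  in_win <- !is.na(q) & q >= w[1] & q <= w[2]
  # year-only receipt dates: keep when the whole year is inside the window
  year_only <- !full & !is.na(demo$receipt_year)
  yr <- demo$receipt_year[year_only]
  in_win[year_only] <- (4L * yr + 1L) >= w[1] & (4L * yr + 4L) <= w[2]

  in_ids <- demo$primaryid[in_win]
  drg <- reports$drugs
  hit <- drg$role == "suspect" &
    norm_key(drg$drug_name) == norm_key(drug) &
    norm_key(drg$indication_pt) %in% norm_key(indication_pts)
  cohort_ids <- intersect(in_ids, unique(drg$primaryid[hit & !is.na(hit)]))
  background_ids <- setdiff(in_ids, cohort_ids)

  list(cohort = subset_reports(reports, cohort_ids),
       background = subset_reports(reports, background_ids),
       n_excluded_window = sum(!in_win))
}
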