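# Hand-built fixtures used across the unit tests. Everything is constructed
# in code so counts can be verified by inspection.

toy_dict <- function() {
  meddra_dictionary(system.file("extdata", "meddra_toy.csv", package = "faersdp"))
}

toy_synonyms <- function() {
  synonym_table(system.file("extdata", "drug_synonyms.csv", package = "faersdp"))
}

# one fully populated report, parameterized so fixtures stay terse
mk_report <- function(primaryid, caseid = primaryid, caseversion = 1,
                      receipt = "2020-02-10", sex = "female", age = 40,
                      country = "US", reporter = "physician",
                      drug = "ustekinumab", role = "suspect",
                      indication = "Crohn's disease", route = "Subcutaneous",
                      therapy_start = NA, pts = "Abscess", event_dates = NA,
                      outcomes = character(0)) {
  list(
    demo = tibble::tibble(
      primaryid = primaryid, caseid = caseid, caseversion = caseversion,
      receipt_date = as.Date(receipt),
      receipt_year = as.integer(format(as.Date(receipt), "%Y")),
      sex = sex, age_years = age, country = country, reporter = reporter),
    drugs = tibble::tibble(
      primaryid = primaryid, drug_name = drug, role = role, route = route,
      indication_pt = indication, therapy_start = as.Date(therapy_start)),
    reactions = tibble::tibble(
      primaryid = primaryid, pt = pts,
      event_date = as.Date(rep_len(event_dates, length(pts)))),
    outcomes = if (length(outcomes))
      tibble::tibble(primaryid = primaryid, outcome = outcomes)
    else NULL
  )
}

bind_reports <- function(...) {
  parts <- list(...)
  pull <- function(field) dplyr::bind_rows(lapply(parts, `[[`, field))
  faers_data(pull("demo"), pull("drugs"), pull("reactions"), pull("outcomes"))
}

# six well-formed reports spanning cohort/background/window situations
six_reports <- function() {
  bind_reports(
    mk_report("1000011", pts = c("Abscess", "Abdominal pain"),
              therapy_start = "2020-01-01", event_dates = "2020-03-21",
              outcomes = c("HO", "DE")),
    mk_report("1000021", receipt = "2019-06-05", sex = "male", age = 31,
              pts = "Headache", outcomes = "OT"),
    mk_report("1000031", receipt = "2021-11-20", drug = "STELARA",
              pts = c("Diarrhoea", "Nausea")),
    mk_report("1000041", receipt = "2020-07-14", drug = "adalimumab",
              indication = "Rheumatoid arthritis", pts = "Rash"),
    mk_report("1000051", receipt = "2016-05-02", pts = "Fatigue"),
    mk_report("1000061", receipt = "2022-02-01", indication = "Psoriasis",
              pts = c("Abscess", "Pruritus"), outcomes = "HO")
  )
}

# a small two-arm database with hand-countable contingency tables:
# 5 cohort reports, 3 mentioning "X" (one of them twice), and 95 background
# reports of which 10 mention "X"
contingency_fixture <- function() {
  coh <- lapply(1:5, function(i) {
    pts <- if (i <= 3) c("X", if (i == 1) "X", "Y") else "Y"
    mk_report(sprintf("C%03d1", i), receipt = "2020-05-01", pts = pts)
  })
  bg <- lapply(1:95, function(i) {
    pts <- if (i <= 10) c("X", "Z") else "Z"
    mk_report(sprintf("B%03d1", i), receipt = "2020-05-01",
              drug = "adalimumab", indication = "Rheumatoid arthritis",
              pts = pts)
  })
  do.call(bind_reports, c(coh, bg))
}

split_fixture <- function(fd = contingency_fixture()) {
  filter_cohort(fd, "ustekinumab", "Crohn's disease", c("2016Q4", "2023Q4"))
}

# draw (a, E) cells from a known gamma-mixture prior: the independent route
# used to validate the MGPS fit
simulate_cells <- function(n, prior, seed, e_range = c(0.1, 50)) {
  set.seed(seed)
  comp <- stats::rbinom(n, 1, prior$w)
  lam <- ifelse(comp == 1,
                stats::rgamma(n, prior$alpha1, prior$beta1),
                stats::rgamma(n, prior$alpha2, prior$beta2))
  E <- exp(stats::runif(n, log(e_range[1]), log(e_range[2])))
  list(a = stats::rpois(n, lam * E), E = E)
}

# vectorized builder: one report per row with a single PT, a DE outcome for
# the first `deaths` of each block; fast enough for 40k+ reports
bulk_cohort <- function(pt, total, deaths = 0, sex = "female",
                        year = 2020, prefix = "B") {
  n <- sum(total)
  pid <- sprintf("%s%07d1", prefix, seq_len(n))
  demo <- tibble::tibble(
    primaryid = pid, caseid = substr(pid, 1, nchar(pid) - 1), caseversion = 1L,
    receipt_date = as.Date(paste0(rep(year, length.out = n), "-06-15")),
    receipt_year = rep(year, length.out = n),
    sex = rep(sex, length.out = n), age_years = NA_real_,
    country = "US", reporter = "physician")
  reactions <- tibble::tibble(primaryid = pid, pt = rep(pt, total),
                              event_date = as.Date(NA))
  die <- unlist(mapply(function(t, d) seq_len(t) <= d, total, deaths,
                       SIMPLIFY = FALSE))
  outcomes <- tibble::tibble(primaryid = pid[die], outcome = "DE")
  faers_data(demo, NULL, reactions, outcomes)
}
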