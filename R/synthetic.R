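#' Default preferred-term catalog for the synthetic generator
#'
#' A catalog of preferred terms with their system organ classes and
#' per-report background reporting rates, loosely shaped like the adverse
#' event profile of a biologic used in inflammatory bowel disease: frequent
#' administration/ineffectiveness terms, a sizeable infectious and
#' gastrointestinal block, and rare cardiac, hepatobiliary and neoplastic
#' terms. Rates are per-report Bernoulli probabilities; they sum to about
#' 1.7 events per report.
#'
#' @return a tibble with columns `pt`, `soc`, `background_rate`.
#' @export
default_pt_catalog <- function() {
  rows <- list(
    c("Off label use", "Injury, poisoning and procedural complications", 0.10),
    c("Product dose omission issue", "Injury, poisoning and procedural complications", 0.07),
    c("Incorrect dose administered", "Injury, poisoning and procedural complications", 0.03),
    c("Accidental exposure to product", "Injury, poisoning and procedural complications", 0.02),
    c("Infusion related reaction", "Injury, poisoning and procedural complications", 0.02),
    c("Drug ineffective", "General disorders and administration site conditions", 0.12),
    c("Fatigue", "General disorders and administration site conditions", 0.07),
    c("Injection site pain", "General disorders and administration site conditions", 0.05),
    c("Condition aggravated", "General disorders and administration site conditions", 0.05),
    c("Pyrexia", "General disorders and administration site conditions", 0.035),
    c("Diarrhoea", "Gastrointestinal disorders", 0.06),
    c("Abdominal pain", "Gastrointestinal disorders", 0.055),
    c("Nausea", "Gastrointestinal disorders", 0.05),
    c("Vomiting", "Gastrointestinal disorders", 0.04),
    c("Haematochezia", "Gastrointestinal disorders", 0.009),
    c("Intestinal obstruction", "Gastrointestinal disorders", 0.007),
    c("Frequent bowel movements", "Gastrointestinal disorders", 0.006),
    c("Fistula", "Gastrointestinal disorders", 0.004),
    c("Intestinal stenosis", "Gastrointestinal disorders", 0.002),
    c("Nasopharyngitis", "Infections and infestations", 0.045),
    c("Upper respiratory tract infection", "Infections and infestations", 0.04),
    c("Lower respiratory tract infection", "Infections and infestations", 0.018),
    c("Cellulitis", "Infections and infestations", 0.011),
    c("Abscess", "Infections and infestations", 0.010),
    c("Clostridium difficile infection", "Infections and infestations", 0.009),
    c("Kidney infection", "Infections and infestations", 0.007),
    c("Gastrointestinal infection", "Infections and infestations", 0.005),
    c("Postoperative wound infection", "Infections and infestations", 0.004),
    c("Anal abscess", "Infections and infestations", 0.003),
    c("Headache", "Nervous system disorders", 0.06),
    c("Dizziness", "Nervous system disorders", 0.035),
    c("Migraine", "Nervous system disorders", 0.01),
    c("Rash", "Skin and subcutaneous tissue disorders", 0.045),
    c("Pruritus", "Skin and subcutaneous tissue disorders", 0.035),
    c("Alopecia", "Skin and subcutaneous tissue disorders", 0.018),
    c("Psoriasis", "Skin and subcutaneous tissue disorders", 0.012),
    c("Arthralgia", "Musculoskeletal and connective tissue disorders", 0.05),
    c("Back pain", "Musculoskeletal and connective tissue disorders", 0.03),
    c("Myalgia", "Musculoskeletal and connective tissue disorders", 0.018),
    c("Palpitations", "Cardiac disorders", 0.007),
    c("Myocardial infarction", "Cardiac disorders", 0.0035),
    c("Cardiac failure", "Cardiac disorders", 0.0025),
    c("Cough", "Respiratory, thoracic and mediastinal disorders", 0.03),
    c("Dyspnoea", "Respiratory, thoracic and mediastinal disorders", 0.025),
    c("Skin cancer", "Neoplasms benign, malignant and unspecified (incl cysts and polyps)", 0.0035),
    c("Basal cell carcinoma", "Neoplasms benign, malignant and unspecified (incl cysts and polyps)", 0.0025),
    c("Lymphoma", "Neoplasms benign, malignant and unspecified (incl cysts and polyps)", 0.0018),
    c("Cholelithiasis", "Hepatobiliary disorders", 0.0028),
    c("Cholangitis", "Hepatobiliary disorders", 0.0012),
    c("Weight decreased", "Investigations", 0.02),
    c("Drug level decreased", "Investigations", 0.005),
    c("Faecal calprotectin increased", "Investigations", 0.0015),
    c("Anxiety", "Psychiatric disorders", 0.02),
    c("Depression", "Psychiatric disorders", 0.018),
    c("Hypertension", "Vascular disorders", 0.02),
    c("Deep vein thrombosis", "Vascular disorders", 0.003),
    c("Vision blurred", "Eye disorders", 0.008),
    c("Nephrolithiasis", "Renal and urinary disorders", 0.0045),
    c("Anaemia", "Blood and lymphatic system disorders", 0.014),
    c("Hypersensitivity", "Immune system disorders", 0.01),
    c("Decreased appetite", "Metabolism and nutrition disorders", 0.014)
  )
  tibble::tibble(
    pt = vapply(rows, `[`, "", 1),
    soc = vapply(rows, `[`, "", 2),
    background_rate = as.numeric(vapply(rows, `[`, "", 3))
  )
}

#' Configuration for the synthetic report-database generator
#'
#' Bundles and validates every knob of [generate_reports()]. Defaults
#' describe the benchmark conditions used throughout the package's
#' validation: a cohort of 5,000 target-drug reports against a background of
#' 100,000, the [default_pt_catalog()] reporting rates, a 5% case
#' duplication rate, and demographic missingness in the range seen in
#' spontaneous-report data (sex ~7%, age ~37%, onset dates ~35%).
#'
#' @param n_cohort,n_background number of cohort / background cases.
#' @param pt_catalog tibble `pt`, `soc`, `background_rate` (rates in (0,1]).
#' @param planted data frame `pt`, `rate_ratio` of cohort reporting-rate
#'   elevations (`rate_ratio` > 0; 1 means no elevation), or `NULL`.
#' @param duplicate_rate fraction of cases emitted a second time with an
#'   incremented case version.
#' @param missing_rates named list of missingness fractions for `sex`,
#'   `age`, `country`, `event_date`, `therapy_start`.
#' @param death_rate_by_soc named vector of per-SOC death probabilities; the
#'   `.default` entry covers unlisted SOCs.
#' @param tto_meanlog,tto_sdlog log-normal parameters of the time-to-onset
#'   distribution in days.
#' @param drug,indication_pt canonical target drug and cohort indication.
#' @param window_start,window_end receipt-date range (`Date`).
#' @param seed master seed; every random stream is derived from it, so a
#'   fixed seed gives byte-identical output.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_cohort = 5000, n_background = 100000,
                         pt_catalog = default_pt_catalog(),
                         planted = NULL,
                         duplicate_rate = 0.05,
                         missing_rates = list(sex = 0.07, age = 0.37,
                                              country = 0.02,
                                              event_date = 0.35,
                                              therapy_start = 0.30),
                         death_rate_by_soc = c(
                           "Cardiac disorders" = 0.075,
                           "Neoplasms benign, malignant and unspecified (incl cysts and polyps)" = 0.058,
                           "Hepatobiliary disorders" = 0.022,
                           "Infections and infestations" = 0.020,
                           ".default" = 0.006),
                         tto_meanlog = log(60), tto_sdlog = 1.6,
                         drug = "ustekinumab",
                         indication_pt = "Crohn's disease",
                         window_start = as.Date("2016-10-01"),
                         window_end = as.Date("2023-12-31"),
                         seed = 20260101) {
  chk <- function(ok, field) {
    if (!isTRUE(ok)) stop("invalid synth_config field: ", field, call. = FALSE)
  }
  chk(is.numeric(n_cohort) && n_cohort > 0, "n_cohort")
  chk(is.numeric(n_background) && n_background > 0, "n_background")
  pt_catalog <- tibble::as_tibble(pt_catalog)
  chk(all(c("pt", "soc", "background_rate") %in% names(pt_catalog)), "pt_catalog")
  chk(all(pt_catalog$background_rate > 0 & pt_catalog$background_rate <= 1),
      "pt_catalog$background_rate")
  chk(!anyDuplicated(pt_catalog$pt), "pt_catalog$pt")
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    chk(all(c("pt", "rate_ratio") %in% names(planted)), "planted")
    chk(all(planted$rate_ratio > 0), "planted$rate_ratio")
    chk(all(planted$pt %in% pt_catalog$pt), "planted$pt")
    # an elevated rate must still be a probability
    idx <- match(planted$pt, pt_catalog$pt)
    chk(all(pt_catalog$background_rate[idx] * planted$rate_ratio <= 1),
        "planted$rate_ratio (elevated rate exceeds 1)")
  }
  chk(duplicate_rate >= 0 && duplicate_rate < 1, "duplicate_rate")
  for (f in c("sex", "age", "country", "event_date", "therapy_start")) {
    chk(!is.null(missing_rates[[f]]) && missing_rates[[f]] >= 0 &&
          missing_rates[[f]] <= 1, paste0("missing_rates$", f))
  }
  chk(all(death_rate_by_soc >= 0 & death_rate_by_soc <= 1), "death_rate_by_soc")
  chk(".default" %in% names(death_rate_by_soc), "death_rate_by_soc$.default")
  chk(is.finite(tto_meanlog) && tto_sdlog > 0, "tto_meanlog/tto_sdlog")
  chk(inherits(window_start, "Date") && inherits(window_end, "Date") &&
        window_start <= window_end, "window_start/window_end")
  chk(is.numeric(seed) && abs(seed) < 2^31 - 10, "seed")
  structure(list(
    n_cohort = as.integer(n_cohort), n_background = as.integer(n_background),
    pt_catalog = pt_catalog, planted = planted,
    duplicate_rate = duplicate_rate, missing_rates = missing_rates,
    death_rate_by_soc = death_rate_by_soc,
    tto_meanlog = tto_meanlog, tto_sdlog = tto_sdlog,
    drug = drug, indication_pt = indication_pt,
    window_start = window_start, window_end = window_end,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a synthetic FAERS-like report database with known ground truth
#'
#' Emits a [faers_data] collection of `n_cohort + n_background` cases plus
#' version duplicates. Cohort cases carry the target drug as suspect with
#' the target indication; background cases carry other drugs (a small
#' fraction carry the target drug for a *different* indication, exercising
#' the indication filter). Each report's PT set is drawn per-PT Bernoulli at
#' `background_rate`, multiplied by the planted `rate_ratio` for planted PTs
#' in cohort reports; reports that would end up with no reaction are
#' redrawn. Demographics, outcome codes (death probability driven by the
#' report's SOCs), receipt/therapy/event dates and duplicate case versions
#' follow the configuration.
#'
#' Each field group (demographics, PT sets, dates, drugs, outcomes,
#' duplication) consumes its own RNG stream derived from the master seed, so
#' extending one group never perturbs the others, and the caller's RNG state
#' is untouched.
#'
#' @param config a [synth_config()].
#' @return a list: `reports` (a [faers_data]), `truth` (tibble `pt`,
#'   `rate_ratio` of planted elevations).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n <- cfg$n_cohort + cfg$n_background
  is_cohort <- seq_len(n) <= cfg$n_cohort
  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  cat_pt <- cfg$pt_catalog$pt
  cat_soc <- cfg$pt_catalog$soc
  n_pt <- length(cat_pt)

  # --- stream 1: PT sets ----------------------------------------------------
  rr <- rep(1, n_pt)
  if (!is.null(cfg$planted)) {
    rr[match(cfg$planted$pt, cat_pt)] <- cfg$planted$rate_ratio
  }
  memb <- with_seed(cfg$seed + 1L, {
    m <- matrix(FALSE, n, n_pt)
    for (j in seq_len(n_pt)) {
      p <- cfg$pt_catalog$background_rate[j]
      pj <- ifelse(is_cohort, min(p * rr[j], 1), p)
      m[, j] <- stats::runif(n) < pj
    }
    # resample empty reports until every report has at least one reaction
    for (iter in 1:200) {
      empty <- which(rowSums(m) == 0L)
      if (length(empty) == 0L) break
      for (j in seq_len(n_pt)) {
        p <- cfg$pt_catalog$background_rate[j]
        pj <- ifelse(is_cohort[empty], min(p * rr[j], 1), p)
        m[empty, j] <- stats::runif(length(empty)) < pj
      }
    }
    if (any(rowSums(m) == 0L)) {
      stop("failed to draw non-empty PT sets; rates too small", call. = FALSE)
    }
    m
  })
  reac_idx <- which(memb, arr.ind = TRUE)
  reac_idx <- reac_idx[order(reac_idx[, 1], reac_idx[, 2]), , drop = FALSE]

  # --- stream 2: demographics ----------------------------------------------
  demo_fields <- with_seed(cfg$seed + 2L, {
    sex <- sample(c("female", "male"), n, TRUE, prob = c(0.62, 0.38))
    sex[stats::runif(n) < cfg$missing_rates$sex] <- "unspecified"
    age <- round(pmin(pmax(stats::rnorm(n, 45, 18), 1), 95))
    age[stats::runif(n) < cfg$missing_rates$age] <- NA
    country <- sample(c("US", "CA", "GB", "AU", "FR", "DE", "JP"), n, TRUE,
                      prob = c(0.55, 0.22, 0.08, 0.03, 0.04, 0.04, 0.04))
    country[stats::runif(n) < cfg$missing_rates$country] <- NA
    reporter <- sample(c("consumer", "pharmacist", "physician",
                         "other-health-professional", "unspecified"),
                       n, TRUE, prob = c(0.42, 0.34, 0.15, 0.08, 0.01))
    list(sex = sex, age = age, country = country, reporter = reporter)
  })

  # --- stream 3: dates ------------------------------------------------------
  dates <- with_seed(cfg$seed + 3L, {
    span <- as.integer(cfg$window_end - cfg$window_start)
    receipt <- cfg$window_start + sample.int(span + 1L, n, TRUE) - 1L
    ther_lag <- round(stats::rlnorm(n, log(180), 0.9))
    therapy_start <- receipt - ther_lag
    tto <- round(stats::rlnorm(nrow(reac_idx), cfg$tto_meanlog, cfg$tto_sdlog))
    event <- pmin(therapy_start[reac_idx[, 1]] + tto, receipt[reac_idx[, 1]])
    event[stats::runif(nrow(reac_idx)) < cfg$missing_rates$event_date] <- NA
    therapy_start[stats::runif(n) < cfg$missing_rates$therapy_start] <- NA
    list(receipt = receipt, therapy_start = therapy_start, event = event)
  })

  # --- stream 4: drugs ------------------------------------------------------
  other_drugs <- c("adalimumab", "infliximab", "vedolizumab", "tofacitinib",
                   "methotrexate", "azathioprine", "prednisone", "mesalazine",
                   "secukinumab", "etanercept")
  other_indic <- c("Rheumatoid arthritis", "Ulcerative colitis", "Psoriasis",
                   "Psoriatic arthropathy", "Ankylosing spondylitis")
  drug_tab <- with_seed(cfg$seed + 4L, {
    name <- character(n); indi <- character(n); route <- character(n)
    name[is_cohort] <- cfg$drug
    indi[is_cohort] <- cfg$indication_pt
    route[is_cohort] <- sample(c("Subcutaneous", "Intravenous", NA), cfg$n_cohort,
                               TRUE, prob = c(0.80, 0.14, 0.06))
    nb <- cfg$n_background
    # ~3% of background cases report the target drug for another indication
    other_uste <- stats::runif(nb) < 0.03
    name[!is_cohort] <- ifelse(other_uste, cfg$drug,
                               sample(other_drugs, nb, TRUE))
    indi[!is_cohort] <- sample(other_indic, nb, TRUE)
    route[!is_cohort] <- sample(c("Oral", "Subcutaneous", "Intravenous", NA),
                                nb, TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
    suspect <- tibble::tibble(case = seq_len(n), drug_name = name,
                              role = "suspect", route = route,
                              indication_pt = indi,
                              therapy_start = dates$therapy_start)
    # ~40% of reports also list one concomitant drug
    has_con <- which(stats::runif(n) < 0.4)
    conco <- tibble::tibble(case = has_con,
                            drug_name = sample(other_drugs, length(has_con), TRUE),
                            role = "concomitant",
                            route = NA_character_,
                            indication_pt = NA_character_,
                            therapy_start = as.Date(NA))
    out <- rbind(suspect, conco)
    out[order(out$case), ]
  })

  # --- stream 5: outcomes ---------------------------------------------------
  soc_by_case <- split(cat_soc[reac_idx[, 2]], reac_idx[, 1])
  drate <- cfg$death_rate_by_soc
  p_death <- vapply(soc_by_case, function(socs) {
    r <- drate[socs]
    r[is.na(r)] <- drate[[".default"]]
    max(r)
  }, 0)[as.character(seq_len(n))]
  p_death[is.na(p_death)] <- drate[[".default"]]
  outc_tab <- with_seed(cfg$seed + 5L, {
    de <- stats::runif(n) < p_death
    ho <- stats::runif(n) < 0.30
    lt <- stats::runif(n) < 0.015
    ot <- stats::runif(n) < 0.60
    tibble::tibble(case = c(which(de), which(ho), which(lt), which(ot)),
                   outcome = rep(c("DE", "HO", "LT", "OT"),
                                 c(sum(de), sum(ho), sum(lt), sum(ot))))
  })

  # --- stream 6: duplicate case versions -----------------------------------
  dup <- with_seed(cfg$seed + 6L, {
    idx <- which(stats::runif(n) < cfg$duplicate_rate)
    list(idx = idx,
         lag = if (length(idx)) sample(20:400, length(idx), TRUE) else integer(0))
  })

  primaryid <- paste0(caseid, "1")
  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    receipt_date = dates$receipt,
    receipt_year = as.integer(format(dates$receipt, "%Y")),
    sex = demo_fields$sex, age_years = demo_fields$age,
    country = demo_fields$country, reporter = demo_fields$reporter
  )
  drugs <- tibble::tibble(
    primaryid = primaryid[drug_tab$case], drug_name = drug_tab$drug_name,
    role = drug_tab$role, route = drug_tab$route,
    indication_pt = drug_tab$indication_pt,
    therapy_start = drug_tab$therapy_start
  )
  reactions <- tibble::tibble(
    primaryid = primaryid[reac_idx[, 1]], pt = cat_pt[reac_idx[, 2]],
    event_date = dates$event
  )
  outcomes <- tibble::tibble(primaryid = primaryid[outc_tab$case],
                             outcome = outc_tab$outcome)

  if (length(dup$idx)) {
    sel <- dup$idx
    receipt2 <- pmin(dates$receipt[sel] + dup$lag, cfg$window_end)
    pid2 <- paste0(caseid[sel], "2")
    demo2 <- demo[sel, ]
    demo2$primaryid <- pid2
    demo2$caseversion <- 2L
    demo2$receipt_date <- receipt2
    demo2$receipt_year <- as.integer(format(receipt2, "%Y"))
    clone <- function(tab) {
      sub <- tab[tab$primaryid %in% primaryid[sel], ]
      sub$primaryid <- paste0(substr(sub$primaryid, 1, 8), "2")
      sub
    }
    demo <- rbind(demo, demo2)
    drugs <- rbind(drugs, clone(drugs))
    reactions <- rbind(reactions, clone(reactions))
    outcomes <- rbind(outcomes, clone(outcomes))
  }

  truth <- if (is.null(cfg$planted)) {
    tibble::tibble(pt = character(0), rate_ratio = numeric(0))
  } else cfg$planted
  list(reports = faers_data(demo, drugs, reactions, outcomes), truth = truth)
}

#' End-to-end planted-signal recovery benchmark
#'
#' Runs the whole pipeline on one synthetic database — generate,
#' deduplicate, cohort split, contingency tables, prior fit, all four
#' statistics, combined criterion — and scores the detections against the
#' generator's ground truth: **sensitivity** is the fraction of planted PTs
#' flagged by the combined criterion, and the **false-positive rate** is the
#' fraction of unplanted PTs with at least `min_reports` cohort reports that
#' are flagged.
#'
#' @param config a [synth_config()] (sensitivity is `NA` when nothing is
#'   planted).
#' @param min_reports minimum cohort count for a PT to enter the
#'   false-positive denominator (matches the signal gate).
#' @return a list: `sensitivity`, `false_positive_rate`, `results` (the
#'   evaluated statistics table), `counts` (reports at each pipeline step).
#' @export
end_to_end_recovery <- function(config, min_reports = 3) {
  gen <- generate_reports(config)
  dedup <- deduplicate(gen$reports)
  win <- c(format_quarter(config$window_start), format_quarter(config$window_end))
  split <- filter_cohort(dedup, config$drug, config$indication_pt, win)
  tables <- build_tables(split$cohort, split$background, level = "pt")
  res <- evaluate_signals(compute_dispro(tables))
  planted <- gen$truth$pt[gen$truth$rate_ratio > 1]
  on_planted <- res[res$event %in% planted, ]
  off_planted <- res[!res$event %in% planted & res$n_reports >= min_reports, ]
  list(
    sensitivity = if (length(planted)) mean(on_planted$signal) else NA_real_,
    false_positive_rate = if (nrow(off_planted)) mean(off_planted$signal) else 0,
    results = res,
    counts = list(generated = n_reports(gen$reports),
                  deduplicated = n_reports(dedup),
                  cohort = n_reports(split$cohort),
                  background = n_reports(split$background))
  )
}

format_quarter <- function(date) {
  sprintf("%dQ%d", as.integer(format(date, "%Y")),
          (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L)
}
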