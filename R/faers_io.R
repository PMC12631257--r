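#' A collection of spontaneous safety reports
#'
#' The in-memory representation of a FAERS-style report database: four linked
#' tidy tables keyed by `primaryid` (one physical report version). A logical
#' case may appear as several versions under one `caseid`; [deduplicate()]
#' reduces to one row per case.
#'
#' * `demo` — one row per report: `primaryid`, `caseid`, `caseversion`,
#'   `receipt_date` (FDA receipt; `NA` when only partially dated),
#'   `receipt_year`, `sex` (`"female"`, `"male"`, `"unspecified"`),
#'   `age_years`, `country`, `reporter` (`"consumer"`, `"pharmacist"`,
#'   `"physician"`, `"other-health-professional"`, `"unspecified"`).
#' * `drugs` — one row per reported drug: `primaryid`, `drug_name`, `role`
#'   (`"suspect"` or `"concomitant"`), `route`, `indication_pt`,
#'   `therapy_start`.
#' * `reactions` — one row per reported adverse event: `primaryid`, `pt`,
#'   `event_date`.
#' * `outcomes` — one row per outcome code: `primaryid`, `outcome`
#'   (`DE`, `LT`, `HO`, `DS`, `CA`, `RI`, `OT`).
#'
#' Reports without any reaction are dropped at construction (a report with no
#' adverse event carries no signal information); the number dropped is
#' reported via a message and recorded in the `dropped_no_reaction`
#' attribute. Child-table rows whose `primaryid` has no `demo` row are
#' discarded, and all child tables are ordered to follow `demo` so that a
#' write/read round trip reproduces the object exactly.
#'
#' @param demo,drugs,reactions,outcomes data frames as described above;
#'   missing child tables may be passed as `NULL`.
#' @return an object of class `faers_data`.
#' @export
faers_data <- function(demo, drugs = NULL, reactions = NULL, outcomes = NULL) {
  demo <- tibble::as_tibble(demo)
  need <- c("primaryid", "caseid", "caseversion", "receipt_date", "receipt_year",
            "sex", "age_years", "country", "reporter")
  miss <- setdiff(need, names(demo))
  assert_that(length(miss) == 0L,
              paste0("demo table is missing column(s): ", paste(miss, collapse = ", ")))
  demo$primaryid <- as.character(demo$primaryid)
  demo$caseid <- as.character(demo$caseid)
  demo$caseversion <- as.integer(demo$caseversion)
  demo$caseversion[is.na(demo$caseversion)] <- 1L
  assert_that(all(demo$caseversion >= 1L), "caseversion must be >= 1")
  assert_that(!anyDuplicated(demo$primaryid), "primaryid must be unique in demo")
  demo$receipt_date <- as.Date(demo$receipt_date)
  demo$receipt_year <- as.integer(demo$receipt_year)
  demo$age_years <- as.numeric(demo$age_years)
  demo$sex <- ifelse(demo$sex %in% c("female", "male"), demo$sex, "unspecified")
  ok_rep <- c("consumer", "pharmacist", "physician", "other-health-professional")
  demo$reporter <- ifelse(demo$reporter %in% ok_rep, demo$reporter, "unspecified")
  demo <- demo[need]

  empty_chr <- character(0)
  # a zero-column frame (e.g. from binding empty pieces) counts as absent
  blank <- function(x) if (!is.null(x) && !"primaryid" %in% names(x)) NULL else x
  drugs <- blank(drugs); reactions <- blank(reactions); outcomes <- blank(outcomes)
  drugs <- tibble::as_tibble(drugs %||% tibble::tibble(
    primaryid = empty_chr, drug_name = empty_chr, role = empty_chr,
    route = empty_chr, indication_pt = empty_chr,
    therapy_start = as.Date(empty_chr)))
  for (col in c("drug_name", "role", "route", "indication_pt")) {
    if (is.null(drugs[[col]])) drugs[[col]] <- NA_character_
    drugs[[col]] <- as.character(drugs[[col]])
  }
  drugs$primaryid <- as.character(drugs$primaryid)
  drugs$therapy_start <- as.Date(drugs$therapy_start %||% NA)
  drugs <- drugs[c("primaryid", "drug_name", "role", "route", "indication_pt",
                   "therapy_start")]

  reactions <- tibble::as_tibble(reactions %||% tibble::tibble(
    primaryid = empty_chr, pt = empty_chr, event_date = as.Date(empty_chr)))
  assert_that(all(c("primaryid", "pt") %in% names(reactions)),
              "reactions table needs columns 'primaryid' and 'pt'")
  reactions$primaryid <- as.character(reactions$primaryid)
  reactions$pt <- as.character(reactions$pt)
  reactions$event_date <- as.Date(reactions$event_date %||% NA)
  reactions <- reactions[c("primaryid", "pt", "event_date")]
  reactions <- reactions[!is.na(reactions$pt) & reactions$pt != "", ]

  outcomes <- tibble::as_tibble(outcomes %||% tibble::tibble(
    primaryid = empty_chr, outcome = empty_chr))
  outcomes$primaryid <- as.character(outcomes$primaryid)
  outcomes$outcome <- as.character(outcomes$outcome)
  outcomes <- outcomes[c("primaryid", "outcome")]
  outcomes <- outcomes[!is.na(outcomes$outcome) & outcomes$outcome != "", ]

  # reports must carry at least one reaction
  has_reac <- demo$primaryid %in% reactions$primaryid
  n_drop <- sum(!has_reac)
  if (n_drop > 0) {
    message(n_drop, " report(s) without reactions dropped at ingestion")
    demo <- demo[has_reac, ]
  }

  keep <- function(tab) {
    tab <- tab[tab$primaryid %in% demo$primaryid, ]
    tab[order(match(tab$primaryid, demo$primaryid)), ]
  }
  structure(
    list(demo = demo, drugs = keep(drugs), reactions = keep(reactions),
         outcomes = keep(outcomes)),
    class = "faers_data",
    dropped_no_reaction = n_drop
  )
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data> ", nrow(x$demo), " reports (",
      length(unique(x$demo$caseid)), " cases), ",
      nrow(x$reactions), " reactions, ", nrow(x$drugs), " drug rows\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname faers_data
#' @param x a `faers_data` object.
n_reports <- function(x) {
  stopifnot(inherits(x, "faers_data"))
  nrow(x$demo)
}

# subset a faers_data by primaryid, preserving demo order
subset_reports <- function(x, primaryids) {
  demo <- x$demo[x$demo$primaryid %in% primaryids, ]
  keep <- function(tab) {
    tab <- tab[tab$primaryid %in% demo$primaryid, ]
    tab[order(match(tab$primaryid, demo$primaryid)), ]
  }
  structure(list(demo = demo, drugs = keep(x$drugs),
                 reactions = keep(x$reactions), outcomes = keep(x$outcomes)),
            class = "faers_data")
}

faers_file_roles <- c("DEMO", "DRUG", "REAC", "INDI", "OUTC", "THER")

resolve_faers_paths <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    files <- list.files(paths, full.names = TRUE)
    base <- toupper(sub("[0-9Qq_.].*$", "", basename(files)))
    base <- substr(base, 1, 4)
    found <- files[match(faers_file_roles, base)]
    names(found) <- faers_file_roles
    return(found[!is.na(found)])
  }
  nm <- toupper(names(paths) %||% character(0))
  assert_that(length(nm) == length(paths) && all(nm %in% faers_file_roles),
              paste0("paths must be a directory or a vector named with ",
                     paste(faers_file_roles, collapse = "/")))
  names(paths) <- nm
  paths
}

read_delim_checked <- function(path, delim, required_cols, label) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    stop("file ", label, " (", path, ") is empty", call. = FALSE)
  }
  cols <- norm_key(strsplit(header, delim, fixed = TRUE)[[1]])
  miss <- setdiff(required_cols, cols)
  if (length(miss)) {
    stop("malformed ", label, " header at line 1 of ", path,
         ": missing column(s) ", paste(miss, collapse = ", "),
         " (is the file '", delim, "'-delimited?)", call. = FALSE)
  }
  tab <- readr::read_delim(path, delim = delim, trim_ws = TRUE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  names(tab) <- norm_key(names(tab))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    message(nrow(probs), " malformed row(s) skipped in ", label,
            " (first at line ", probs$row[1] + 1L, ")")
    tab <- tab[setdiff(seq_len(nrow(tab)), unique(probs$row)), ]
  }
  tab
}

map_code <- function(x, map, default) {
  out <- unname(map[toupper(trimws(as.character(x)))])
  out[is.na(out)] <- default
  out
}

#' Read a report database from disk
#'
#' Two on-disk dialects are supported:
#'
#' * `"faers-ascii"` — the FAERS quarterly layout: up to six `"$"`-delimited
#'   tables (`DEMO`, `DRUG`, `REAC`, `INDI`, `OUTC`, `THER`) linked by
#'   `primaryid`. `DEMO` and `REAC` are mandatory. Drug indications and
#'   therapy start dates are joined from `INDI`/`THER` via the drug sequence
#'   number. Dates use the FAERS partial formats (see [faers_date()]).
#' * `"normalized-csv"` — the package's own three-file layout
#'   (`reports.csv`, `drugs.csv`, `reactions.csv`) written by
#'   [write_reports()]; report-level outcome codes are a `;`-separated field
#'   of `reports.csv`. This dialect round-trips a [faers_data] object exactly.
#'
#' @param paths a directory containing the dialect's files, or a character
#'   vector of file paths named by table (`DEMO`, `DRUG`, ... for FAERS
#'   ASCII).
#' @param dialect `"normalized-csv"` or `"faers-ascii"`.
#' @return a [faers_data] object.
#' @export
read_reports <- function(paths, dialect = c("normalized-csv", "faers-ascii")) {
  dialect <- match.arg(dialect)
  if (dialect == "normalized-csv") read_reports_csv(paths) else read_reports_ascii(paths)
}

read_reports_ascii <- function(paths) {
  paths <- resolve_faers_paths(paths)
  for (mand in c("DEMO", "REAC")) {
    if (!mand %in% names(paths) || !file.exists(paths[[mand]])) {
      stop("mandatory FAERS file ", mand, " is missing", call. = FALSE)
    }
  }
  demo_raw <- read_delim_checked(paths[["DEMO"]], "$",
                                 c("primaryid", "caseid", "caseversion", "fda_dt"),
                                 "DEMO")
  reac_raw <- read_delim_checked(paths[["REAC"]], "$", c("primaryid", "pt"), "REAC")
  if (nrow(reac_raw) == 0L) {
    stop("mandatory FAERS file REAC contains no reaction rows", call. = FALSE)
  }

  age <- suppressWarnings(as.numeric(demo_raw$age %||% NA))
  if (!is.null(demo_raw$age_cod)) {
    cod <- toupper(trimws(demo_raw$age_cod))
    age <- age / ifelse(cod == "MON", 12,
                 ifelse(cod == "DY", 365.25,
                 ifelse(cod == "WK", 52.18,
                 ifelse(cod == "HR", 8766, 1))))
    age <- ifelse(cod == "DEC", age * 10, age)
  }
  demo <- tibble::tibble(
    primaryid = demo_raw$primaryid,
    caseid = demo_raw$caseid,
    caseversion = suppressWarnings(as.integer(demo_raw$caseversion)),
    receipt_date = faers_date(demo_raw$fda_dt),
    receipt_year = faers_year(demo_raw$fda_dt),
    sex = map_code(demo_raw$sex %||% demo_raw$gndr_cod %||% NA,
                   c(F = "female", M = "male"), "unspecified"),
    age_years = age,
    country = dplyr::na_if(trimws(demo_raw$occr_country %||% NA_character_), ""),
    reporter = map_code(demo_raw$occp_cod %||% NA,
                        c(CN = "consumer", PH = "pharmacist", MD = "physician",
                          HP = "other-health-professional"),
                        "unspecified")
  )

  reactions <- tibble::tibble(
    primaryid = reac_raw$primaryid,
    pt = reac_raw$pt,
    event_date = faers_date(reac_raw$event_dt %||% NA)
  )

  drugs <- NULL
  if ("DRUG" %in% names(paths)) {
    drug_raw <- read_delim_checked(paths[["DRUG"]], "$",
                                   c("primaryid", "drugname", "role_cod"), "DRUG")
    drug_raw$drug_seq <- drug_raw$drug_seq %||% as.character(seq_len(nrow(drug_raw)))
    drugs <- tibble::tibble(
      primaryid = drug_raw$primaryid,
      drug_seq = drug_raw$drug_seq,
      drug_name = drug_raw$drugname,
      role = map_code(drug_raw$role_cod,
                      c(PS = "suspect", SS = "suspect", SUSPECT = "suspect",
                        C = "concomitant", I = "concomitant",
                        CONCOMITANT = "concomitant"),
                      "concomitant"),
      route = dplyr::na_if(trimws(drug_raw$route %||% NA_character_), ""),
      indication_pt = NA_character_,
      therapy_start = as.Date(NA)
    )
    if ("INDI" %in% names(paths)) {
      indi <- read_delim_checked(paths[["INDI"]], "$",
                                 c("primaryid", "indi_drug_seq", "indi_pt"), "INDI")
      idx <- match(paste(drugs$primaryid, drugs$drug_seq),
                   paste(indi$primaryid, indi$indi_drug_seq))
      drugs$indication_pt <- indi$indi_pt[idx]
    }
    if ("THER" %in% names(paths)) {
      ther <- read_delim_checked(paths[["THER"]], "$",
                                 c("primaryid", "dsg_drug_seq", "start_dt"), "THER")
      idx <- match(paste(drugs$primaryid, drugs$drug_seq),
                   paste(ther$primaryid, ther$dsg_drug_seq))
      drugs$therapy_start <- faers_date(ther$start_dt[idx])
    }
    drugs$drug_seq <- NULL
  }

  outcomes <- NULL
  if ("OUTC" %in% names(paths)) {
    outc <- read_delim_checked(paths[["OUTC"]], "$", c("primaryid", "outc_cod"), "OUTC")
    outcomes <- tibble::tibble(primaryid = outc$primaryid, outcome = toupper(outc$outc_cod))
  }

  faers_data(demo, drugs, reactions, outcomes)
}

csv_report_cols <- readr::cols(
  primaryid = readr::col_character(),
  caseid = readr::col_character(),
  caseversion = readr::col_integer(),
  receipt_date = readr::col_date(format = "%Y-%m-%d"),
  receipt_year = readr::col_integer(),
  sex = readr::col_character(),
  age_years = readr::col_double(),
  country = readr::col_character(),
  reporter = readr::col_character(),
  outcomes = readr::col_character()
)

read_reports_csv <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    paths <- c(reports = file.path(paths, "reports.csv"),
               drugs = file.path(paths, "drugs.csv"),
               reactions = file.path(paths, "reactions.csv"))
  }
  for (mand in c("reports", "reactions")) {
    if (!mand %in% names(paths) || !file.exists(paths[[mand]])) {
      stop("mandatory normalized-csv file '", mand, ".csv' is missing", call. = FALSE)
    }
  }
  rep <- readr::read_csv(paths[["reports"]], col_types = csv_report_cols, progress = FALSE)
  outcomes <- tidyr::separate_rows(rep[c("primaryid", "outcomes")], "outcomes", sep = ";")
  outcomes <- dplyr::rename(outcomes[!is.na(outcomes$outcomes) & outcomes$outcomes != "", ],
                            outcome = "outcomes")
  rea <- readr::read_csv(paths[["reactions"]], col_types = readr::cols(
    primaryid = readr::col_character(), pt = readr::col_character(),
    event_date = readr::col_date(format = "%Y-%m-%d")), progress = FALSE)
  drg <- NULL
  if ("drugs" %in% names(paths) && file.exists(paths[["drugs"]])) {
    drg <- readr::read_csv(paths[["drugs"]], col_types = readr::cols(
      primaryid = readr::col_character(), drug_name = readr::col_character(),
      role = readr::col_character(), route = readr::col_character(),
      indication_pt = readr::col_character(),
      therapy_start = readr::col_date(format = "%Y-%m-%d")), progress = FALSE)
  }
  faers_data(rep[setdiff(names(rep), "outcomes")], drg, rea, outcomes)
}

#' Write a report database to disk
#'
#' @param reports a [faers_data] object.
#' @param dir output directory (created if needed).
#' @inheritParams read_reports
#' @return invisibly, the paths written.
#' @export
write_reports <- function(reports, dir, dialect = c("normalized-csv", "faers-ascii")) {
  stopifnot(inherits(reports, "faers_data"))
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (dialect == "normalized-csv") {
    oc <- dplyr::summarise(dplyr::group_by(reports$outcomes, .data$primaryid),
                           outcomes = paste(.data$outcome, collapse = ";"))
    rep <- dplyr::left_join(reports$demo, oc, by = "primaryid")
    paths <- c(reports = file.path(dir, "reports.csv"),
               drugs = file.path(dir, "drugs.csv"),
               reactions = file.path(dir, "reactions.csv"))
    readr::write_csv(rep, paths[["reports"]], na = "", progress = FALSE)
    readr::write_csv(reports$drugs, paths[["drugs"]], na = "", progress = FALSE)
    readr::write_csv(reports$reactions, paths[["reactions"]], na = "", progress = FALSE)
  } else {
    fmt <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))
    demo <- reports$demo
    demo_out <- tibble::tibble(
      primaryid = demo$primaryid, caseid = demo$caseid,
      caseversion = demo$caseversion, fda_dt = fmt(demo$receipt_date),
      sex = map_code(demo$sex, c(FEMALE = "F", MALE = "M"), "UNK"),
      age = demo$age_years, age_cod = "YR",
      occr_country = demo$country,
      occp_cod = map_code(demo$reporter,
                          c(CONSUMER = "CN", PHARMACIST = "PH", PHYSICIAN = "MD",
                            `OTHER-HEALTH-PROFESSIONAL` = "HP"), "")
    )
    # partial receipt dates: emit the year so faers_year() still recovers it
    only_year <- is.na(demo$receipt_date) & !is.na(demo$receipt_year)
    demo_out$fda_dt[only_year] <- as.character(demo$receipt_year[only_year])
    drugs <- dplyr::mutate(dplyr::group_by(reports$drugs, .data$primaryid),
                           drug_seq = dplyr::row_number())
    drug_out <- tibble::tibble(
      primaryid = drugs$primaryid, drug_seq = drugs$drug_seq,
      drugname = drugs$drug_name,
      role_cod = ifelse(drugs$role == "suspect", "PS", "C"),
      route = drugs$route
    )
    indi_out <- tibble::tibble(primaryid = drugs$primaryid,
                               indi_drug_seq = drugs$drug_seq,
                               indi_pt = drugs$indication_pt)
    indi_out <- indi_out[!is.na(indi_out$indi_pt), ]
    ther_out <- tibble::tibble(primaryid = drugs$primaryid,
                               dsg_drug_seq = drugs$drug_seq,
                               start_dt = fmt(drugs$therapy_start))
    ther_out <- ther_out[ther_out$start_dt != "", ]
    reac_out <- tibble::tibble(primaryid = reports$reactions$primaryid,
                               pt = reports$reactions$pt,
                               event_dt = fmt(reports$reactions$event_date))
    outc_out <- tibble::tibble(primaryid = reports$outcomes$primaryid,
                               outc_cod = reports$outcomes$outcome)
    paths <- file.path(dir, paste0(faers_file_roles, ".txt"))
    names(paths) <- faers_file_roles
    tabs <- list(DEMO = demo_out, DRUG = drug_out, REAC = reac_out,
                 INDI = indi_out, OUTC = outc_out, THER = ther_out)
    for (role in faers_file_roles) {
      readr::write_delim(tabs[[role]], paths[[role]], delim = "$", na = "",
                         progress = FALSE)
    }
  }
  invisible(paths)
}
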