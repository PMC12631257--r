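#' Deduplicate a report database to one row per case
#'
#' FAERS reissues updated versions of a case; only the latest belongs in an
#' analysis. Two rules are applied, in order:
#'
#' 1. **Version rule.** Among reports sharing a `caseid`, keep the highest
#'    `caseversion`; ties are broken by latest `receipt_date`, then by the
#'    first occurrence in input order.
#' 2. **Cross-id rule.** Reports with distinct `caseid`s but identical
#'    content on the tuple (sex, age, country, drug-name set, PT set,
#'    event-date set) are taken to be the same case filed twice; the one
#'    with the earliest `receipt_date` is kept (ties by input order).
#'    Matching is exact — no fuzzy comparison — so the rule is deterministic
#'    and conservative.
#'
#' The operation is idempotent. Counts removed by each rule are attached as
#' attributes `removed_version` and `removed_crossid`.
#'
#' @param reports a [faers_data] object.
#' @return a [faers_data] object with one report per case.
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "faers_data"))
  demo <- reports$demo
  n0 <- nrow(demo)
  demo$.ord <- seq_len(n0)

  # rule 1: highest caseversion per caseid, ties by latest receipt, then input order
  keyed <- dplyr::arrange(demo, .data$caseid, dplyr::desc(.data$caseversion),
                          dplyr::desc(!is.na(.data$receipt_date)),
                          dplyr::desc(.data$receipt_date), .data$.ord)
  keep1 <- keyed$primaryid[!duplicated(keyed$caseid)]
  demo1 <- demo[demo$primaryid %in% keep1, ]
  removed_version <- n0 - nrow(demo1)

  # rule 2: collapse distinct caseids with identical content tuples
  sig_of <- function(tab, col) {
    x <- split(as.character(tab[[col]]), tab$primaryid)
    vapply(x, function(v) paste(sort(v), collapse = "\x1f"), "")
  }
  drg <- reports$drugs[reports$drugs$primaryid %in% demo1$primaryid, ]
  rea <- reports$reactions[reports$reactions$primaryid %in% demo1$primaryid, ]
  drug_sig <- sig_of(drg, "drug_name")
  pt_sig <- sig_of(rea, "pt")
  evt_sig <- sig_of(rea[!is.na(rea$event_date), ], "event_date")
  key <- paste(
    demo1$sex, demo1$age_years, demo1$country,
    drug_sig[demo1$primaryid], pt_sig[demo1$primaryid], evt_sig[demo1$primaryid],
    sep = "\x1e"
  )
  ord2 <- order(key,
                is.na(demo1$receipt_date), demo1$receipt_date, demo1$.ord)
  first_of_key <- !duplicated(key[ord2])
  keep2 <- demo1$primaryid[ord2][first_of_key]
  removed_crossid <- nrow(demo1) - length(keep2)

  out <- subset_reports(reports, keep2)
  attr(out, "removed_version") <- removed_version
  attr(out, "removed_crossid") <- removed_crossid
  out
}
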