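#' Build 2x2 contingency tables for every drug-event pair
#'
#' For each adverse event observed in the cohort, counts the classical
#' four-grid table against the background:
#'
#' * `a` — cohort reports mentioning the event,
#' * `b` — cohort reports not mentioning it,
#' * `c` — background reports mentioning it,
#' * `d` — background reports not mentioning it,
#'
#' with `N = a+b+c+d` and the expected count under independence
#' `E = (a+b)(a+c)/N`. The counting unit is the distinct (report, event)
#' pair: a report contributes at most once to a given event even when the
#' same PT is recorded twice, and at SOC level a report counts once per
#' distinct SOC among its PTs. Tables are emitted for every event with
#' `a >= 1`; the minimum-count gate for signal evaluation is applied
#' downstream so descriptive counts stay complete.
#'
#' @param cohort,background disjoint deduplicated [faers_data] objects (see
#'   [filter_cohort()]).
#' @param level `"pt"` or `"soc"`.
#' @param dictionary a [meddra_dictionary()]; required for `level = "soc"`.
#' @return a tibble with columns `event`, `level`, `a`, `b`, `c`, `d`, `N`,
#'   `E`, sorted by decreasing `a`.
#' @export
build_tables <- function(cohort, background, level = c("pt", "soc"),
                         dictionary = NULL) {
  stopifnot(inherits(cohort, "faers_data"), inherits(background, "faers_data"))
  level <- match.arg(level)
  n_coh <- n_reports(cohort)
  n_bg <- n_reports(background)
  assert_that(n_coh > 0, "empty cohort: no denominator for disproportionality")
  assert_that(n_bg > 0, "empty background: no comparator population")

  event_pairs <- function(x) {
    ev <- x$reactions[c("primaryid", "pt")]
    ev$event <- ev$pt
    if (level == "soc") {
      assert_that(!is.null(dictionary), "a dictionary is required at SOC level")
      ev$event <- map_pt_to_soc(dictionary, ev$pt)
    }
    dplyr::distinct(ev, .data$primaryid, .data$event)
  }
  coh_pairs <- event_pairs(cohort)
  bg_pairs <- event_pairs(background)

  a_tab <- dplyr::count(coh_pairs, .data$event, name = "a")
  c_tab <- dplyr::count(bg_pairs, .data$event, name = "c")
  tab <- dplyr::left_join(a_tab, c_tab, by = "event")
  tab$c[is.na(tab$c)] <- 0L
  tab <- dplyr::mutate(tab,
    level = level,
    b = n_coh - .data$a,
    d = n_bg - .data$c,
    N = n_coh + n_bg,
    E = (.data$a + .data$b) * (.data$a + .data$c) / .data$N
  )
  tab <- tab[order(-tab$a, tab$event), ]
  tibble::as_tibble(tab[c("event", "level", "a", "b", "c", "d", "N", "E")])
}
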