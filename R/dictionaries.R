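#' PT to SOC dictionary
#'
#' A MedDRA-style dictionary mapping each preferred term (PT) to its single
#' primary system organ class (SOC). Lookups are case-insensitive after
#' whitespace normalization. The full licensed MedDRA terminology cannot be
#' redistributed; the package ships a small open dictionary
#' (`system.file("extdata", "meddra_toy.csv", package = "faersdp")`) covering
#' the terms used by the synthetic generator and the worked examples, and any
#' table with `pt` and `soc` columns can be supplied instead.
#'
#' @param x a data frame with columns `pt` and `soc`, or a path to a CSV file
#'   with those columns.
#' @return an object of class `meddra_dict`.
#' @examples
#' d <- meddra_dictionary(data.frame(pt = "Abscess",
#'                                   soc = "Infections and infestations"))
#' map_pt_to_soc(d, c("abscess", "Qqqq"))
#' @export
meddra_dictionary <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  assert_that(all(c("pt", "soc") %in% names(x)),
              "dictionary must have columns 'pt' and 'soc'")
  x$key <- norm_key(x$pt)
  conflicting <- dplyr::n_distinct(paste(x$key, x$soc)) > dplyr::n_distinct(x$key)
  assert_that(!conflicting, "each PT must map to exactly one SOC")
  x <- dplyr::distinct(x, .data$key, .keep_all = TRUE)
  structure(
    list(pt = as.character(x$pt), soc = as.character(x$soc), key = x$key),
    class = "meddra_dict"
  )
}

#' @export
print.meddra_dict <- function(x, ...) {
  cat("<meddra_dict> ", length(x$pt), " PTs across ",
      length(unique(x$soc)), " SOCs\n", sep = "")
  invisible(x)
}

#' Map preferred terms to system organ classes
#'
#' Unmapped PTs return the sentinel `"UNMAPPED"` (and are reported via a
#' message) rather than being dropped, so downstream SOC aggregates never
#' silently lose events.
#'
#' @param dictionary a [meddra_dictionary()].
#' @param pt character vector of preferred terms.
#' @return character vector of SOC names, `"UNMAPPED"` where unknown.
#' @export
map_pt_to_soc <- function(dictionary, pt) {
  stopifnot(inherits(dictionary, "meddra_dict"))
  idx <- match(norm_key(pt), dictionary$key)
  soc <- dictionary$soc[idx]
  miss <- is.na(idx) & !is.na(pt)
  if (any(miss)) {
    soc[miss] <- "UNMAPPED"
    message(sum(miss), " PT value(s) not in dictionary, mapped to UNMAPPED: ",
            paste(utils::head(unique(pt[miss]), 5), collapse = ", "))
  }
  soc
}

#' Drug synonym table
#'
#' Maps raw verbatim drug strings (trade names, spelling variants) to one
#' canonical ingredient name, standing in for a full drug-name
#' standardization engine. Matching is case- and whitespace-insensitive;
#' strings with no entry pass through unchanged.
#'
#' @param x a data frame with columns `raw` and `canonical`, or a path to a
#'   CSV file with those columns.
#' @return an object of class `synonym_table`.
#' @export
synonym_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  assert_that(all(c("raw", "canonical") %in% names(x)),
              "synonym table must have columns 'raw' and 'canonical'")
  x <- dplyr::distinct(x, key = norm_key(.data$raw), .keep_all = TRUE)
  structure(
    list(raw = as.character(x$raw), canonical = as.character(x$canonical),
         key = x$key),
    class = "synonym_table"
  )
}

#' Standardize drug names in a report collection
#'
#' Replaces every drug name that matches a synonym-table entry with its
#' canonical form; unmatched names are left untouched and the distinct
#' unmatched strings are reported once via a message.
#'
#' @param reports a [faers_data] object.
#' @param synonyms a [synonym_table()].
#' @return the report collection with standardized `drug_name` values.
#' @export
standardize_drug_names <- function(reports, synonyms) {
  stopifnot(inherits(reports, "faers_data"), inherits(synonyms, "synonym_table"))
  nm <- reports$drugs$drug_name
  idx <- match(norm_key(nm), synonyms$key)
  hit <- !is.na(idx)
  nm[hit] <- synonyms$canonical[idx[hit]]
  unmatched <- unique(nm[!hit])
  if (length(unmatched)) {
    message(length(unmatched), " drug name(s) had no synonym entry and were kept as-is: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "")
  }
  reports$drugs$drug_name <- nm
  reports
}
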