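#' Run the full signal-detection pipeline from a declarative config
#'
#' Orchestrates the complete flow — obtain reports (synthetic generation or
#' ingestion from disk), standardize drug names, deduplicate, split into
#' cohort and background by drug/indication/window, build PT- and SOC-level
#' contingency tables, compute the four disproportionality statistics, apply
#' the combined signal criterion, and write the descriptive tables — into an
#' output directory of CSV files plus a run log:
#'
#' * `counts.csv` — report counts at each filter step (monotone
#'   non-increasing),
#' * `signals.csv` — every PT-level event with statistics and flags,
#' * `signals_top.csv` — signal-positive events ranked by report count,
#' * `soc_signals.csv` — the same statistics at SOC level,
#' * `table1.csv` — demographic/TTO summary blocks,
#' * `table4.csv` — death proportion by SOC,
#' * `yearly.csv` — reports per receipt year,
#' * `run.log` — parameter values and dropped-record counts.
#'
#' The configuration is validated before any I/O, outputs are written to a
#' temporary directory and moved into place only on success, and all
#' randomness is governed by the config seed, so a rerun with the same
#' config produces byte-identical CSVs.
#'
#' @param config a YAML file path or an equivalent named list. Recognized
#'   keys: `mode` (`"simulate"` or `"ingest"`), `seed`, `simulate` (options
#'   passed to [synth_config()], with `planted` as a list of
#'   `{pt, rate_ratio}` entries), `input` (`path`, `dialect`), `dictionary`
#'   and `synonyms` (CSV paths; the bundled toy files by default), `drug`,
#'   `indication_pts`, `window`, `thresholds` (`min_reports`, `ror_min`,
#'   `prr_min`, `ic025_min`, `ebgm05_min`), `top`.
#' @param out_dir output directory; must not already contain a `run.log`
#'   unless `overwrite = TRUE`.
#' @param overwrite replace existing outputs.
#' @return invisibly, a list with the output paths, the step counts, and the
#'   evaluated PT-level results.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    assert_that(file.exists(config), paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a YAML path or a named list")
  cfg <- validate_pipeline_config(config)
  assert_that(overwrite || !file.exists(file.path(out_dir, "run.log")),
              paste0("output directory already holds a run: ", out_dir))

  log_lines <- c("faersdp pipeline run",
                 paste0("  mode: ", cfg$mode),
                 paste0("  drug: ", cfg$drug),
                 paste0("  indication_pts: ", paste(cfg$indication_pts, collapse = "; ")),
                 paste0("  window: ", paste(cfg$window, collapse = " .. ")),
                 paste0("  seed: ", cfg$seed),
                 paste0("  thresholds: ", paste(names(cfg$thresholds),
                                                unlist(cfg$thresholds),
                                                sep = "=", collapse = ", ")))

  if (cfg$mode == "simulate") {
    sim_args <- cfg$simulate %||% list()
    if (!is.null(sim_args$planted)) {
      sim_args$planted <- dplyr::bind_rows(lapply(sim_args$planted, tibble::as_tibble))
    }
    sim_args$seed <- cfg$seed
    scfg <- do.call(synth_config, sim_args)
    gen <- generate_reports(scfg)
    reports <- gen$reports
    log_lines <- c(log_lines, paste0("  simulated cases: ", scfg$n_cohort, " cohort + ",
                                     scfg$n_background, " background"))
  } else {
    reports <- read_reports(cfg$input$path, cfg$input$dialect)
  }
  n_extracted <- n_reports(reports)

  dict <- meddra_dictionary(cfg$dictionary)
  syn <- synonym_table(cfg$synonyms)
  reports <- standardize_drug_names(reports, syn)

  dedup <- deduplicate(reports)
  log_lines <- c(log_lines,
                 paste0("  removed by version rule: ", attr(dedup, "removed_version")),
                 paste0("  removed by cross-id rule: ", attr(dedup, "removed_crossid")))

  split <- filter_cohort(dedup, cfg$drug, cfg$indication_pts, cfg$window)
  log_lines <- c(log_lines,
                 paste0("  excluded outside window: ", split$n_excluded_window))
  counts <- tibble::tibble(
    step = c("extracted", "deduplicated", "in_window", "cohort"),
    n = c(n_extracted, n_reports(dedup),
          n_reports(split$cohort) + n_reports(split$background),
          n_reports(split$cohort))
  )

  th <- cfg$thresholds
  pt_tables <- build_tables(split$cohort, split$background, "pt")
  pt_res <- evaluate_signals(compute_dispro(pt_tables),
                             min_reports = th$min_reports, ror_min = th$ror_min,
                             prr_min = th$prr_min, ic025_min = th$ic025_min,
                             ebgm05_min = th$ebgm05_min)
  soc_tables <- build_tables(split$cohort, split$background, "soc", dict)
  soc_res <- evaluate_signals(compute_dispro(soc_tables),
                              min_reports = th$min_reports, ror_min = th$ror_min,
                              prr_min = th$prr_min, ic025_min = th$ic025_min,
                              ebgm05_min = th$ebgm05_min)
  top_res <- rank_signals(pt_res, by = "n_reports", top = cfg$top)

  demog <- summarize_demographics(split$cohort, cfg$drug)
  tto <- summarize_tto(split$cohort, cfg$drug)
  table1 <- dplyr::bind_rows(c(
    lapply(demog[c("sex", "age_band", "reporter", "country", "route",
                   "outcomes", "year")],
           function(b) tibble::tibble(level = as.character(b$level),
                                      n = b$n, pct = b$pct)),
    list(tto = tibble::tibble(level = tto$bins$level, n = tto$bins$n,
                              pct = tto$bins$pct))), .id = "block")
  table4 <- death_proportion_by_soc(split$cohort, dict)
  yearly <- yearly_counts(split$cohort)

  tmp <- tempfile("faersdp_out_")
  dir.create(tmp)
  files <- c(counts = "counts.csv", signals = "signals.csv",
             signals_top = "signals_top.csv", soc_signals = "soc_signals.csv",
             table1 = "table1.csv", table4 = "table4.csv", yearly = "yearly.csv")
  readr::write_csv(counts, file.path(tmp, files["counts"]), progress = FALSE)
  readr::write_csv(round_display(pt_res), file.path(tmp, files["signals"]), progress = FALSE)
  readr::write_csv(round_display(top_res), file.path(tmp, files["signals_top"]), progress = FALSE)
  readr::write_csv(round_display(soc_res), file.path(tmp, files["soc_signals"]), progress = FALSE)
  readr::write_csv(table1, file.path(tmp, files["table1"]), progress = FALSE)
  readr::write_csv(table4, file.path(tmp, files["table4"]), progress = FALSE)
  readr::write_csv(yearly, file.path(tmp, files["yearly"]), progress = FALSE)
  writeLines(log_lines, file.path(tmp, "run.log"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c(files, "run.log")) {
    file.copy(file.path(tmp, f), file.path(out_dir, f), overwrite = TRUE)
  }
  unlink(tmp, recursive = TRUE)

  invisible(list(paths = file.path(out_dir, unname(c(files, "run.log"))),
                 counts = counts, results = pt_res))
}

# estimates are displayed rounded to 2 decimals; full precision is kept
# internally and used for all flag evaluation
round_display <- function(res) {
  num <- c("ror", "ror_lo", "ror_hi", "prr", "prr_lo", "prr_hi",
           "ic", "ic025", "ebgm", "ebgm05")
  for (col in intersect(num, names(res))) res[[col]] <- round(res[[col]], 2)
  res
}

validate_pipeline_config <- function(config) {
  mode <- config$mode %||% "simulate"
  assert_that(mode %in% c("simulate", "ingest"),
              "config$mode must be 'simulate' or 'ingest'")
  if (mode == "ingest") {
    assert_that(!is.null(config$input$path), "config$input$path is required")
    assert_that((config$input$dialect %||% "normalized-csv") %in%
                  c("normalized-csv", "faers-ascii"),
                "config$input$dialect must be normalized-csv or faers-ascii")
    config$input$dialect <- config$input$dialect %||% "normalized-csv"
  }
  window <- unlist(config$window %||% c("2016Q4", "2023Q4"))
  w <- parse_quarter(window)  # errors on malformed quarters
  assert_that(length(w) == 2L && w[1] <= w[2],
              "config$window must be c(start, end) with start <= end")
  defaults <- list(min_reports = 3, ror_min = 3, prr_min = 2,
                   ic025_min = 0, ebgm05_min = 2)
  th <- utils::modifyList(defaults, config$thresholds %||% list())
  list(
    mode = mode,
    seed = as.integer(config$seed %||% 20260101),
    simulate = config$simulate,
    input = config$input,
    dictionary = config$dictionary %||%
      system.file("extdata", "meddra_toy.csv", package = "faersdp"),
    synonyms = config$synonyms %||%
      system.file("extdata", "drug_synonyms.csv", package = "faersdp"),
    drug = config$drug %||% "ustekinumab",
    indication_pts = unlist(config$indication_pts %||% "Crohn's disease"),
    window = window,
    thresholds = th,
    top = config$top %||% 30
  )
}
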