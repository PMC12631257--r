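#' Apply per-method signal thresholds and the combined criterion
#'
#' The standard quadruple criterion for a positive signal, evaluated on
#' full-precision statistics (never on rounded display values):
#'
#' 1. ROR: `a >= 3`, `ROR >= 3` and lower 95% CI bound `> 1`;
#' 2. PRR: `a >= 3`, `PRR >= 2` and lower 95% CI bound `> 1`;
#' 3. BCPNN: `IC025 > 0` (strict);
#' 4. EBGM: `EBGM05 > 2` (strict).
#'
#' The combined flag `signal` requires all four. A statistic that is
#' non-computable (`NA`, e.g. a zero cell blocked the ROR) fails its flag.
#' Raising any threshold can only shrink the signal set.
#'
#' @param results a tibble from [compute_dispro()].
#' @param min_reports minimum observed count `a` for the frequentist flags.
#' @param ror_min,prr_min,ic025_min,ebgm05_min thresholds as listed above.
#' @return `results` with added logical columns `flag_ror`, `flag_prr`,
#'   `flag_ic`, `flag_ebgm`, `signal`.
#' @export
evaluate_signals <- function(results, min_reports = 3, ror_min = 3,
                             prr_min = 2, ic025_min = 0, ebgm05_min = 2) {
  need <- c("n_reports", "ror", "ror_lo", "prr", "prr_lo", "ic025", "ebgm05")
  assert_that(all(need %in% names(results)),
              "results must come from compute_dispro()")
  isT <- function(x) !is.na(x) & x
  results$flag_ror <- isT(results$n_reports >= min_reports &
                            results$ror >= ror_min & results$ror_lo > 1)
  results$flag_prr <- isT(results$n_reports >= min_reports &
                            results$prr >= prr_min & results$prr_lo > 1)
  results$flag_ic <- isT(results$ic025 > ic025_min)
  results$flag_ebgm <- isT(results$ebgm05 > ebgm05_min)
  results$signal <- results$flag_ror & results$flag_prr &
    results$flag_ic & results$flag_ebgm
  results
}

#' Rank positive signals
#'
#' Orders the signal-positive rows by report frequency or by ROR,
#' descending; ties are broken by the other key descending, then by event
#' name ascending, and the first `top` rows are returned.
#'
#' @param results an evaluated results tibble (see [evaluate_signals()]).
#' @param by `"n_reports"` or `"ror"`.
#' @param top number of rows to keep; `Inf` keeps all.
#' @return the ranked subset of `results`.
#' @export
rank_signals <- function(results, by = c("n_reports", "ror"), top = 30) {
  by <- match.arg(by)
  assert_that("signal" %in% names(results),
              "results must be evaluated with evaluate_signals() first")
  assert_that(top > 0, "top must be positive")
  other <- if (by == "n_reports") "ror" else "n_reports"
  sig <- results[results$signal, ]
  sig <- sig[order(-sig[[by]], -sig[[other]], sig$event), ]
  utils::head(sig, if (is.finite(top)) top else nrow(sig))
}
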