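#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a*d)/(b*c)`, with the log-scale Woolf interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied: when any cell needed is zero the estimate or its
#' interval is returned as `NA` and flagged non-computable, because silent
#' corrections distort rankings and the minimum-count signal gate makes
#' zero-`a` tables irrelevant for signal detection anyway.
#'
#' @param a,b,c,d integer vectors: cohort-with-event, cohort-without,
#'   background-with, background-without.
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return a tibble with columns `est`, `lo`, `hi`.
#' @examples
#' ror(10, 90, 100, 9900)  # 11.0 (5.56, 21.76)
#' @export
ror <- function(a, b, c, d, z = 1.96) {
  est <- ifelse(b > 0 & c > 0, (a * d) / (b * c), NA_real_)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(est = est,
                 lo = exp(log(est) - z * se),
                 hi = exp(log(est) + z * se))
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`, with log-scale interval
#' `exp(log(PRR) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Zero cells
#' are handled as in [ror()].
#'
#' @inheritParams ror
#' @return a tibble with columns `est`, `lo`, `hi`.
#' @examples
#' prr(10, 90, 100, 9900)  # 10.0
#' @export
prr <- function(a, b, c, d, z = 1.96) {
  est <- ifelse(a + b > 0 & c > 0, (a / (a + b)) / (c / (c + d)), NA_real_)
  ok <- a > 0 & c > 0
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  tibble::tibble(est = est,
                 lo = exp(log(est) - z * se),
                 hi = exp(log(est) + z * se))
}

#' BCPNN information component with lower credibility bound
#'
#' The shrinkage observed-to-expected information component
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E = (a+b)(a+c)/N`, and the
#' closed-form approximation to the 2.5th posterior percentile
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`. The additive 0.5
#' acts as a shrinkage prior pulling small-count cells toward IC = 0, so the
#' statistic is computable for every table, including `a = 0`.
#'
#' @inheritParams ror
#' @return a tibble with columns `ic` and `ic025` (log2 scale).
#' @examples
#' ic_bcpnn(10, 90, 100, 9900)  # IC 2.72, IC025 1.65
#' @export
ic_bcpnn <- function(a, b, c, d) {
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  ic <- log2((a + 0.5) / (E + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  tibble::tibble(ic = ic, ic025 = ic025)
}

#' Monte-Carlo oracle for the information component
#'
#' Posterior-simulation counterpart of [ic_bcpnn()], used to validate the
#' closed form. Under the shrinkage observed-to-expected model the relative
#' reporting rate has posterior `lambda ~ Gamma(a + 0.5, E + 0.5)` (shape,
#' rate); the IC samples are `log2(lambda)`. Returns the Monte-Carlo
#' posterior mean and 2.5th percentile. The closed-form `ic` is the log of
#' the posterior mean rather than the mean of the log, so the two agree only
#' up to a small-count Jensen gap that vanishes as counts grow — which is
#' exactly the convergence the validation tests assert.
#'
#' @inheritParams ror
#' @param draws number of posterior draws (at least 1e5).
#' @param seed integer seed for the draw stream (the caller's RNG state is
#'   left untouched).
#' @return a list with elements `ic` and `ic025`.
#' @export
mc_ic_oracle <- function(a, b, c, d, draws = 1e5, seed = 1L) {
  stopifnot(length(a) == 1L, draws >= 1e5)
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  with_seed(seed, {
    lam <- stats::rgamma(draws, shape = a + 0.5, rate = E + 0.5)
    ic <- log2(lam)
    list(ic = mean(ic), ic025 = unname(stats::quantile(ic, 0.025)))
  })
}

#' Two-component gamma mixture prior for the MGPS shrinker
#'
#' The empirical-Bayes model behind EBGM: each cell's true relative
#' reporting rate `lambda` is drawn from
#' `w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2)` (shape/rate),
#' and the observed count is `a ~ Poisson(lambda * E)`. The canonical
#' starting point `(0.2, 0.1, 2, 4, 1/3)` mixes a diffuse component
#' (admitting large elevations) with a concentrated component near
#' `lambda = 0.5`.
#'
#' @param alpha1,beta1,alpha2,beta2 positive shape and rate parameters.
#' @param w mixture weight of the first component, in (0, 1).
#' @return an object of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, w) {
  assert_that(all(c(alpha1, beta1, alpha2, beta2) > 0),
              "gamma shape/rate parameters must be positive")
  assert_that(w > 0 && w < 1, "mixture weight w must be in (0, 1)")
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf("<mgps_prior> w=%.3f  Gamma(%.3g, %.3g) / Gamma(%.3g, %.3g)  mean=%.3f\n",
              x$w, x$alpha1, x$beta1, x$alpha2, x$beta2, mgps_prior_mean(x)))
  if (!is.null(attr(x, "loglik")))
    cat("  marginal log-likelihood:", format(attr(x, "loglik")), "\n")
  invisible(x)
}

#' @rdname mgps_prior
#' @param prior an `mgps_prior` object.
#' @export
mgps_prior_mean <- function(prior) {
  prior$w * prior$alpha1 / prior$beta1 + (1 - prior$w) * prior$alpha2 / prior$beta2
}

#' Marginal log-likelihood of counts under the MGPS mixture model
#'
#' Integrating the Poisson likelihood over the gamma mixture gives a
#' two-component negative-binomial mixture:
#' `P(a) = w NB(a; alpha1, beta1/(beta1+E)) + (1-w) NB(a; alpha2, beta2/(beta2+E))`.
#'
#' @param prior an [mgps_prior()].
#' @param a,E vectors of observed and expected counts, one element per cell.
#' @return the summed log-likelihood.
#' @export
mgps_loglik <- function(prior, a, E) {
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  sum(logsumexp2(log(prior$w) + l1, log1p(-prior$w) + l2))
}

#' Fit the MGPS prior by maximum marginal likelihood
#'
#' Maximizes [mgps_loglik()] over all five parameters on transformed scales
#' (log for shapes/rates, logit for the weight), so the optimizer is
#' unconstrained. Starts from the canonical point
#' `(0.2, 0.1, 2, 4, 1/3)` plus `n_restarts` random perturbations drawn from
#' a private seeded stream, runs Nelder-Mead from each start, polishes the
#' best with BFGS, and returns the overall best fit.
#'
#' @param a,E vectors of observed and expected counts over all drug-event
#'   cells of the database (at least ~100 cells recommended; with fewer the
#'   five parameters are weakly identified).
#' @param init numeric vector `(alpha1, beta1, alpha2, beta2, w)` for the
#'   primary start.
#' @param n_restarts number of additional random starts.
#' @param restart_seed seed for the restart stream.
#' @return an [mgps_prior()] with attributes `loglik` and `convergence`.
#' @export
fit_mgps_prior <- function(a, E, init = c(0.2, 0.1, 2, 4, 1 / 3),
                           n_restarts = 4, restart_seed = 42L) {
  assert_that(length(a) == length(E) && length(a) >= 2,
              "need matching vectors of observed and expected counts")
  assert_that(all(E > 0), "expected counts must be positive")

  to_theta <- function(p) c(log(p[1:4]), stats::qlogis(p[5]))
  from_theta <- function(th) c(exp(th[1:4]), stats::plogis(th[5]))
  negll <- function(th) {
    p <- from_theta(th)
    if (any(!is.finite(p)) || any(p[1:4] <= 0)) return(1e12)
    ll <- mgps_loglik(mgps_prior(p[1], p[2], p[3], p[4], p[5]), a, E)
    if (!is.finite(ll)) 1e12 else -ll
  }

  starts <- list(to_theta(init))
  if (n_restarts > 0) {
    starts <- c(starts, with_seed(restart_seed, {
      lapply(seq_len(n_restarts), function(i)
        to_theta(init) + stats::rnorm(5, sd = c(1, 1, 1, 1, 0.75)))
    }))
  }

  fits <- lapply(starts, function(th0) {
    tryCatch(stats::optim(th0, negll, method = "Nelder-Mead",
                          control = list(maxit = 2000)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value) && f$value < 1e12,
                 fits)
  if (length(fits) == 0L) {
    stop("MGPS prior fit failed from every start", call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  polished <- tryCatch(stats::optim(best$par, negll, method = "BFGS",
                                    control = list(maxit = 500)),
                       error = function(e) best)
  if (is.finite(polished$value) && polished$value <= best$value) best <- polished
  if (!is.finite(best$value) || best$value >= 1e12) {
    h <- 1e-5
    grad <- vapply(seq_along(best$par), function(k) {
      e_k <- replace(numeric(length(best$par)), k, h)
      (negll(best$par + e_k) - negll(best$par - e_k)) / (2 * h)
    }, 0)
    stop("MGPS prior fit did not converge; best objective ", best$value,
         ", gradient norm ", sqrt(sum(grad^2)), call. = FALSE)
  }

  p <- from_theta(best$par)
  out <- mgps_prior(p[1], p[2], p[3], p[4], p[5])
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Empirical Bayes geometric mean and lower posterior percentile
#'
#' Given the fitted mixture prior, the posterior of a cell's relative
#' reporting rate is again a two-component gamma mixture with components
#' `Gamma(alpha_j + a, beta_j + E)` and data-updated weights proportional to
#' `w_j * NB(a; alpha_j, beta_j/(beta_j+E))`. Then
#' `EBGM = 2^{E[log2 lambda | a]}`, evaluated with the digamma closed form
#' `E[log lambda] = sum_j Q_j (psi(alpha_j + a) - log(beta_j + E))`, and
#' `EBGM05` is the lower posterior percentile (5th by MGPS convention;
#' settable to 2.5th) found by monotone root-finding on the mixture CDF to
#' relative tolerance 1e-8.
#'
#' @param a,E vectors of observed and expected counts.
#' @param prior an [mgps_prior()].
#' @param percentile lower posterior percentile for `ebgm05` (default 0.05).
#' @return a tibble with columns `ebgm` and `ebgm05` (ratio scale).
#' @examples
#' # single-component prior Gamma(2, 4), a = 10, E = 1:
#' # EBGM = exp(digamma(12))/5 ~ 2.301
#' ebgm(10, 1, mgps_prior(2, 4, 2, 4, 1 - 1e-12))
#' @export
ebgm <- function(a, E, prior, percentile = 0.05) {
  stopifnot(inherits(prior, "mgps_prior"), length(a) == length(E))
  assert_that(all(E > 0), "expected counts must be positive")
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  lq1 <- log(prior$w) + stats::dnbinom(a, size = prior$alpha1,
                                       prob = prior$beta1 / (prior$beta1 + E),
                                       log = TRUE)
  lq2 <- log1p(-prior$w) + stats::dnbinom(a, size = prior$alpha2,
                                          prob = prior$beta2 / (prior$beta2 + E),
                                          log = TRUE)
  norm <- logsumexp2(lq1, lq2)
  q1 <- exp(lq1 - norm); q2 <- exp(lq2 - norm)

  elog <- q1 * (digamma(s1) - log(r1)) + q2 * (digamma(s2) - log(r2))
  ebgm_val <- exp(elog)

  eb05 <- vapply(seq_along(a), function(i) {
    if (!is.finite(q1[i]) || !is.finite(q2[i])) {
      stop("EBGM05: posterior weights are degenerate for cell a=", a[i],
           ", E=", E[i], " (invalid prior)", call. = FALSE)
    }
    mix_cdf <- function(x) q1[i] * stats::pgamma(x, s1[i], r1[i]) +
      q2[i] * stats::pgamma(x, s2[i], r2[i])
    qs <- c(stats::qgamma(percentile, s1[i], r1[i]),
            stats::qgamma(percentile, s2[i], r2[i]))
    lo <- min(qs); hi <- max(qs)
    if (hi - lo <= 1e-12 * hi) return(lo)
    # the mixture quantile lies between the component quantiles; pad the
    # bracket for floating-point slack and widen if the CDF is still on the
    # wrong side at an endpoint
    for (pad in 2^(0:40)) {
      lo_p <- lo / pad
      hi_p <- hi * pad
      if (mix_cdf(lo_p) <= percentile && mix_cdf(hi_p) >= percentile) {
        return(stats::uniroot(function(x) mix_cdf(x) - percentile,
                              c(lo_p, hi_p), tol = 1e-8 * max(hi_p, 1))$root)
      }
    }
    stop("EBGM05 root-finder could not bracket the posterior quantile; ",
         "the prior is degenerate for cell a=", a[i], ", E=", E[i],
         call. = FALSE)
  }, 0)

  tibble::tibble(ebgm = ebgm_val, ebgm05 = eb05)
}

#' Compute all four disproportionality statistics for a set of tables
#'
#' Convenience wrapper applying [ror()], [prr()], [ic_bcpnn()] and [ebgm()]
#' to every row of a contingency-table set (see [build_tables()]). When no
#' prior is supplied, the MGPS prior is fitted to the tables themselves via
#' [fit_mgps_prior()] — appropriate when the tables cover all drug-event
#' cells of the database.
#'
#' @param tables a tibble from [build_tables()].
#' @param prior an [mgps_prior()], or `NULL` to fit from `tables`.
#' @param ebgm_percentile lower posterior percentile for `ebgm05`.
#' @return a tibble with one row per event: `event`, `n_reports`, `ror`,
#'   `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `ic`, `ic025`, `ebgm`,
#'   `ebgm05`.
#' @export
compute_dispro <- function(tables, prior = NULL, ebgm_percentile = 0.05) {
  need <- c("event", "a", "b", "c", "d", "N", "E")
  assert_that(all(need %in% names(tables)),
              "tables must come from build_tables()")
  if (is.null(prior)) prior <- fit_mgps_prior(tables$a, tables$E)
  r <- ror(tables$a, tables$b, tables$c, tables$d)
  p <- prr(tables$a, tables$b, tables$c, tables$d)
  i <- ic_bcpnn(tables$a, tables$b, tables$c, tables$d)
  e <- ebgm(tables$a, tables$E, prior, percentile = ebgm_percentile)
  out <- tibble::tibble(
    event = tables$event, n_reports = tables$a,
    ror = r$est, ror_lo = r$lo, ror_hi = r$hi,
    prr = p$est, prr_lo = p$lo, prr_hi = p$hi,
    ic = i$ic, ic025 = i$ic025,
    ebgm = e$ebgm, ebgm05 = e$ebgm05
  )
  attr(out, "prior") <- prior
  out
}
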