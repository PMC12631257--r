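# Reference table used throughout: a=10, b=90, c=100, d=9900
# (E = 100*110/10100 = 1.089109). Closed-form values below were computed
# independently from the printed formulas before being frozen here.

test_that("ROR point estimate and Woolf interval match hand-computed values", {
  r <- ror(10, 90, 100, 9900)
  expect_equal(r$est, 11)                      # (10*9900)/(90*100)
  expect_equal(r$lo, 5.559515, tolerance = 1e-6)
  expect_equal(r$hi, 21.764486, tolerance = 1e-6)
  expect_equal(ror(5, 45, 95, 855)$est, 1)     # a*d = b*c
})

test_that("PRR point estimate and interval match hand-computed values", {
  p <- prr(10, 90, 100, 9900)
  expect_equal(p$est, 10)                      # (10/100)/(100/10000)
  expect_equal(p$lo, 5.382154, tolerance = 1e-6)
  expect_equal(p$hi, 18.579922, tolerance = 1e-6)
  expect_equal(prr(5, 45, 95, 855)$est, 1)
})

test_that("zero cells yield non-computable results, not corrected ones", {
  expect_true(is.na(ror(10, 0, 100, 9900)$est))
  expect_true(is.na(ror(10, 90, 0, 9900)$est))
  expect_true(is.na(prr(10, 90, 0, 10000)$est))
  # a = 0: interval non-computable, IC still defined and negative
  expect_true(is.na(ror(0, 100, 100, 9900)$lo))
  expect_lt(ic_bcpnn(0, 100, 100, 9900)$ic, 0)
})

test_that("confidence bounds bracket the point estimate on all-positive tables", {
  set.seed(33)
  for (i in 1:20) {
    cells <- 1 + stats::rpois(4, lambda = c(20, 200, 300, 5000))
    r <- ror(cells[1], cells[2], cells[3], cells[4])
    p <- prr(cells[1], cells[2], cells[3], cells[4])
    expect_true(r$lo <= r$est && r$est <= r$hi)
    expect_true(p$lo <= p$est && p$est <= p$hi)
  }
})

test_that("shrinkage IC and its lower bound match the closed form", {
  i <- ic_bcpnn(10, 90, 100, 9900)
  expect_equal(i$ic, 2.724099, tolerance = 1e-6)
  expect_equal(i$ic025, 1.646915, tolerance = 1e-6)
  # (a+0.5) = (E+0.5) makes IC exactly zero
  expect_equal(ic_bcpnn(1, 9, 9, 81)$ic, 0)
})

test_that("the Monte-Carlo IC oracle is seeded-deterministic and agrees with the closed form", {
  o1 <- mc_ic_oracle(10, 90, 100, 9900, draws = 1e5, seed = 5)
  o2 <- mc_ic_oracle(10, 90, 100, 9900, draws = 1e5, seed = 5)
  expect_identical(o1, o2)
  ic_cf <- ic_bcpnn(10, 90, 100, 9900)
  expect_lt(abs(o1$ic - ic_cf$ic), 0.15)
  expect_lt(abs(o1$ic025 - ic_cf$ic025), 0.15)
  # the Jensen gap between mean-log and log-mean shrinks with count scale
  o100 <- mc_ic_oracle(1000, 9000, 10000, 990000, draws = 1e5, seed = 5)
  ic100 <- ic_bcpnn(1000, 9000, 10000, 990000)
  expect_lt(abs(o100$ic - ic100$ic), abs(o1$ic - ic_cf$ic))
})

test_that("closed-form IC tracks the oracle across a grid of tables", {
  set.seed(91)
  for (i in 1:20) {
    a <- sample(3:400, 1)
    b <- sample(50:5000, 1)
    c <- sample(50:5000, 1)
    d <- sample(5000:100000, 1)
    cf <- ic_bcpnn(a, b, c, d)
    mc <- mc_ic_oracle(a, b, c, d, draws = 1e5, seed = 100 + i)
    expect_lt(abs(cf$ic - mc$ic), 0.15)
  }
})

test_that("EBGM reproduces the single-component digamma closed form", {
  # degenerate mixture: both components Gamma(2, 4); a = 10, E = 1 gives
  # posterior Gamma(12, 5), so EBGM = exp(psi(12))/5
  prior <- mgps_prior(2, 4, 2, 4, 0.5)
  e <- ebgm(10, 1, prior)
  expect_equal(e$ebgm, exp(digamma(12)) / 5, tolerance = 1e-9)
  expect_equal(e$ebgm, 2.300724, tolerance = 1e-6)
})

test_that("EBGM shrinks extreme observed/expected ratios toward the prior", {
  prior <- mgps_prior(2, 4, 2, 4, 0.5)
  e <- ebgm(1000, 1, prior)
  expect_lt(e$ebgm, 1000)
  expect_true(e$ebgm05 < e$ebgm)
})

test_that("ebgm05 lies below ebgm across random tables and priors", {
  prior <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  set.seed(14)
  a <- stats::rpois(30, 20)
  E <- stats::rgamma(30, 2, 0.2) + 0.05
  e <- ebgm(a, E, prior)
  expect_true(all(e$ebgm05 < e$ebgm))
  expect_true(all(is.finite(e$ebgm)))
})

test_that("root-found ebgm05 matches a posterior Monte-Carlo quantile within 2%", {
  prior <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  for (cell in list(c(a = 10, E = 2), c(a = 60, E = 15), c(a = 4, E = 6))) {
    a <- cell[["a"]]; E <- cell[["E"]]
    e <- ebgm(a, E, prior)
    # independent route: sample the posterior mixture directly
    l1 <- log(prior$w) + stats::dnbinom(a, size = prior$alpha1,
                                        prob = prior$beta1 / (prior$beta1 + E),
                                        log = TRUE)
    l2 <- log(1 - prior$w) + stats::dnbinom(a, size = prior$alpha2,
                                            prob = prior$beta2 / (prior$beta2 + E),
                                            log = TRUE)
    q1 <- 1 / (1 + exp(l2 - l1))
    set.seed(77)
    comp <- stats::rbinom(1e6, 1, q1)
    lam <- ifelse(comp == 1,
                  stats::rgamma(1e6, prior$alpha1 + a, prior$beta1 + E),
                  stats::rgamma(1e6, prior$alpha2 + a, prior$beta2 + E))
    mc_q05 <- unname(stats::quantile(lam, 0.05))
    expect_equal(e$ebgm05, mc_q05, tolerance = 0.02)
  }
})

test_that("the 2.5th-percentile option moves ebgm05 down", {
  prior <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  expect_lt(ebgm(10, 2, prior, percentile = 0.025)$ebgm05,
            ebgm(10, 2, prior, percentile = 0.05)$ebgm05)
})

test_that("all four statistics are non-decreasing in a with b, c, d fixed", {
  prior <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  b <- 500; c <- 300; d <- 50000
  a <- c(3, 8, 20, 50, 120)
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  expect_false(is.unsorted(ror(a, b, c, d)$est))
  expect_false(is.unsorted(prr(a, b, c, d)$est))
  expect_false(is.unsorted(ic_bcpnn(a, b, c, d)$ic))
  expect_false(is.unsorted(ebgm(a, E, prior)$ebgm))
})

test_that("scaling all cells leaves ROR/PRR fixed and narrows their intervals", {
  base <- c(10, 90, 100, 9900)
  for (k in c(2, 10)) {
    s <- base * k
    r0 <- ror(base[1], base[2], base[3], base[4])
    rk <- ror(s[1], s[2], s[3], s[4])
    p0 <- prr(base[1], base[2], base[3], base[4])
    pk <- prr(s[1], s[2], s[3], s[4])
    expect_equal(rk$est, r0$est)
    expect_equal(pk$est, p0$est)
    expect_lt(rk$hi - rk$lo, r0$hi - r0$lo)
    expect_lt(pk$hi - pk$lo, p0$hi - p0$lo)
  }
})

test_that("mgps prior validation rejects bad parameters", {
  expect_error(mgps_prior(-1, 1, 1, 1, 0.5), "positive")
  expect_error(mgps_prior(1, 1, 1, 1, 1), "w must be")
})
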