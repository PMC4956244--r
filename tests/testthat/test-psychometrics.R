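# independent brute-force oracle: lay out the discrete distribution that
# places mass dp_i at the interval midpoints and take its moments directly
sk_oracle <- function(levels, p, lb, ub) {
  lev <- c(lb, levels, ub)
  pp <- c(0, p, 1)
  mids <- (lev[-1] + lev[-length(lev)]) / 2
  mass <- diff(pp)
  m <- sum(mids * mass) / sum(mass)
  list(pss = m, jnd = sqrt(sum(mass * (mids - m)^2) / sum(mass)))
}

test_that("response aggregation conserves counts and ignores row order", {
  resp <- tibble::tibble(
    soa_ms = rep(c(0, 0, 0, 0, 40, -40), 2),
    response = c("light_first", "light_first", "sound_first", "sound_first",
                 "light_first", "sound_first",
                 "sound_first", "light_first", "sound_first", "light_first",
                 "light_first", "sound_first")
  )
  agg <- aggregate_responses(resp, "soa_ms", "light_first")
  expect_s3_class(agg, "psychometric_data")
  expect_equal(sum(agg$n_trials), nrow(resp))
  expect_equal(agg$n_positive[agg$level_ms == 0] / agg$n_trials[agg$level_ms == 0],
               0.5)
  shuffled <- resp[sample(nrow(resp)), ]
  expect_equal(aggregate_responses(shuffled, "soa_ms", "light_first"), agg)
  expect_error(aggregate_responses(resp, "nope", "light_first"), "unknown")
})

test_that("Spearman-Karber reproduces the hand-computed worked examples", {
  d1 <- psychometric_data(c(-100, 0, 100), rep(10, 3), c(0, 5, 10))
  e1 <- sk_estimate(d1)
  expect_equal(e1$pss_ms, 0)
  expect_equal(e1$jnd_ms, 50)
  expect_false(e1$monotonized)

  d2 <- psychometric_data(c(-100, 0, 100), rep(4, 3), c(0, 1, 4))
  e2 <- sk_estimate(d2)
  expect_equal(e2$pss_ms, 25)
  expect_equal(e2$jnd_ms, sqrt(1875))  # ~43.30
})

test_that("Spearman-Karber equals the brute-force discrete-moment oracle", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      K <- sample(3:15, 1)
      levels <- sort(sample(seq(-200, 200, by = 5), K))
      p <- sort(runif(K))
      n <- rep(20, K)     # constant so rounding keeps the proportions monotone
      d <- psychometric_data(levels, n, round(p * n))
      est <- sk_estimate(d)
      pd <- d$n_positive / d$n_trials
      orc <- sk_oracle(levels, pd, -250, 250)
      expect_equal(est$pss_ms, orc$pss, tolerance = 1e-12)
      expect_equal(est$jnd_ms, orc$jnd, tolerance = 1e-12)
      expect_gte(est$pss_ms, -250)
      expect_lte(est$pss_ms, 250)
      expect_gte(est$jnd_ms, 0)
    }
  })
})

test_that("PSS is shift-equivariant and JND shift-invariant; both scale", {
  d <- psychometric_data(c(-100, -30, 0, 60, 100), rep(20, 5),
                         c(1, 6, 11, 17, 19))
  base <- sk_estimate(d)
  shifted <- sk_estimate(
    psychometric_data(d$level_ms + 30, d$n_trials, d$n_positive),
    lower_bound = -220, upper_bound = 280)
  expect_equal(shifted$pss_ms, base$pss_ms + 30)
  expect_equal(shifted$jnd_ms, base$jnd_ms)
  scaled <- sk_estimate(
    psychometric_data(d$level_ms * 2, d$n_trials, d$n_positive),
    lower_bound = -500, upper_bound = 500)
  expect_equal(scaled$pss_ms, base$pss_ms * 2)
  expect_equal(scaled$jnd_ms, base$jnd_ms * 2)
})

test_that("cumulative-Gaussian data recover the mean and SD on a dense grid", {
  mu <- 20; sigma <- 50
  levels <- seq(mu - 5 * sigma, mu + 5 * sigma, by = sigma / 10)
  p <- pnorm(levels, mu, sigma)
  n <- 1e6
  d <- psychometric_data(levels, rep(n, length(levels)), round(p * n))
  est <- sk_estimate(d, lower_bound = mu - 8 * sigma, upper_bound = mu + 8 * sigma)
  expect_lt(abs(est$pss_ms - mu), 0.02 * sigma)
  expect_lt(abs(est$jnd_ms - sigma) / sigma, 0.02)
})

test_that("non-monotone proportions are monotonized by weighted PAVA", {
  d <- psychometric_data(c(-100, -50, 0, 50, 100), rep(10, 5),
                         c(1, 4, 3, 8, 10))
  est <- sk_estimate(d)
  expect_true(est$monotonized)
  expect_gte(est$jnd_ms, 0)

  # equal weights: hand-rolled PAVA must agree with stats::isoreg
  withr::with_seed(5, {
    for (rep in 1:20) {
      y <- runif(12)
      expect_equal(tempreg:::pava_weighted(y, rep(1, 12)),
                   stats::isoreg(y)$yf, tolerance = 1e-10)
    }
  })

  # padding bounds must strictly bracket the levels
  expect_error(sk_estimate(d, lower_bound = -100), "bracket")
  expect_error(sk_estimate(d, upper_bound = 100), "bracket")
})

test_that("bounded probit clips to [.01, .99] before the normal quantile", {
  expect_equal(probit_bounded(0.5), 0)
  expect_equal(probit_bounded(1), qnorm(0.99))
  expect_equal(probit_bounded(0), qnorm(0.01))
  expect_equal(probit_bounded(1), 2.326, tolerance = 1e-3)
  expect_equal(probit_bounded(0.3), qnorm(0.3))
  expect_error(probit_bounded(1.2), "0, 1")
  expect_error(probit_bounded(0.5, lower = 0.9, upper = 0.1), "lower")
})
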