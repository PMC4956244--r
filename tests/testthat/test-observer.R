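test_that("belief initialization centers the prediction one interval ahead", {
  p <- observer_params()
  s <- init_belief(0, p, ioi = 700)
  expect_equal(s$predicted_onset_mean, 700)
  expect_equal(s$predicted_onset_sd, p$initial_prior_sd)
  expect_equal(init_belief(100, p, ioi = 700)$predicted_onset_mean, 800)
})

test_that("fusion is precision-weighted with correct degenerate limits", {
  p <- observer_params(sensory_sd = 30)
  s <- init_belief(0, p)
  s$predicted_onset_mean <- 2800

  # equal precisions: midpoint
  s$predicted_onset_sd <- 30
  f <- fuse(s, 2760, p)
  expect_equal(f$perceived_onset, 2780)
  expect_equal(f$posterior_sd, 30 / sqrt(2))

  # flat prior: the observation wins
  s$predicted_onset_sd <- Inf
  expect_equal(fuse(s, 2760, p)$perceived_onset, 2760)

  # zero-width prior: the prediction wins
  s$predicted_onset_sd <- 0
  expect_equal(fuse(s, 2760, p)$perceived_onset, 2800)
  expect_equal(fuse(s, 2760, p)$posterior_sd, 0)

  # zero sensory noise: the observation wins exactly, even over a
  # zero-width prior (documented dominance convention)
  p0 <- observer_params(sensory_sd = 0)
  s$predicted_onset_sd <- 50
  expect_equal(fuse(s, 2760, p0)$perceived_onset, 2760)
  s$predicted_onset_sd <- 0
  expect_equal(fuse(s, 2760, p0)$perceived_onset, 2760)
  # two infinitely wide components carry no information at all
  pInf <- observer_params(sensory_sd = Inf)
  s$predicted_onset_sd <- Inf
  expect_error(fuse(s, 2760, pInf), "precision")

  # perceived onset always lies between prior mean and observation
  p <- observer_params(sensory_sd = 40)
  for (sd_p in c(5, 40, 200)) {
    s$predicted_onset_sd <- sd_p
    f <- fuse(s, 2700, p)
    expect_true(f$perceived_onset >= 2700 && f$perceived_onset <= 2800)
  }
})

test_that("advancing shifts by the interval estimate and inflates uncertainty", {
  p <- observer_params(interval_sd = 0)
  s <- init_belief(0, p, ioi = 700)
  s2 <- advance(s, 2100, 10, p)
  expect_equal(s2$predicted_onset_mean, 2800)
  expect_equal(s2$predicted_onset_sd, 10)
  p30 <- observer_params(interval_sd = 30)
  expect_equal(advance(s, 2100, 40, p30)$predicted_onset_sd, 50)
})

test_that("perceived anisochrony shrinks deviants by the closed-form weight", {
  # identity without a prior or sensory noise
  sq <- realize_sequence(make_condition(jitter = 0, anisochrony = -40), seed = 1)
  res <- perceive_final(sq, noiseless_flat_params(), seed = 2)
  expect_equal(res$perceived_anisochrony, -40)

  # full regularisation when the prediction is certain
  p_certain <- observer_params(sensory_sd = 30, initial_prior_sd = 0,
                               interval_sd = 0)
  res <- perceive_final(sq, p_certain, seed = 3)
  expect_equal(res$perceived_anisochrony, 0)

  # Monte-Carlo mean matches w * anisochrony within 3 SE
  p <- observer_params(sensory_sd = 30, initial_prior_sd = 80, interval_sd = 20)
  sp <- expected_final_prior_sd(80, 30, 20)    # independent recursion
  w <- sp^2 / (sp^2 + 30^2)
  expect_equal(predicted_sd_at_final(p), sp)
  expect_equal(shrinkage_weight(p), w)
  draws <- withr::with_seed(404, {
    replicate(4000, perceive_final(sq, p)$perceived_anisochrony)
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - w * (-40)), 3 * se)
  # informative prior shrinks: strictly between the deviation and zero
  expect_gt(mean(draws), -40)
  expect_lt(mean(draws), 0)
})

test_that("regularisation is monotone in prior precision", {
  sq <- realize_sequence(make_condition(jitter = 0, anisochrony = -40), seed = 1)
  interval_sds <- c(0, 10, 30, 60, 120)
  w <- vapply(interval_sds, function(v) {
    shrinkage_weight(observer_params(sensory_sd = 30, initial_prior_sd = 80,
                                     interval_sd = v))
  }, numeric(1))
  expect_true(all(diff(w) > 0))  # wider environment -> less shrinkage
  means <- vapply(seq_along(interval_sds), function(i) {
    p <- observer_params(sensory_sd = 30, initial_prior_sd = 80,
                         interval_sd = interval_sds[i])
    withr::with_seed(500 + i,
                     mean(replicate(1500, perceive_final(sq, p)$perceived_anisochrony)))
  }, numeric(1))
  # |E perceived anisochrony| grows (toward 40) as the prior loosens
  expect_true(all(diff(abs(means)) > 0))
})

test_that("environment statistics are learned by exponential smoothing", {
  p <- observer_params(interval_sd = 40, env_learning_rate = 0)
  expect_identical(update_environment(p, c(10, 20, 30)), p)
  p1 <- observer_params(interval_sd = 40, env_learning_rate = 1)
  expect_equal(update_environment(p1, rep(100, 5))$interval_sd, 100)
  p5 <- observer_params(interval_sd = 0, env_learning_rate = 0.5)
  expect_equal(update_environment(p5, rep(100, 3))$interval_sd, 50)
  # RMS, not mean: innovations of mixed sign still widen the estimate
  expect_equal(update_environment(p1, c(-100, 100))$interval_sd, 100)
})

test_that("two-noisy-criteria responses match the analytic psychometric curve", {
  p <- observer_params(criterion_early = -80, criterion_late = 80,
                       criterion_sd_early = 20, criterion_sd_late = 20,
                       lapse_rate = 0)
  expect_equal(respond_regular(0, p, seed = 1), "regular")
  p_sharp <- observer_params(criterion_early = -100, criterion_late = 100,
                             criterion_sd_early = 1e-9, criterion_sd_late = 1e-9,
                             lapse_rate = 0)
  expect_equal(respond_regular(-200, p_sharp, seed = 1), "irregular")
  expect_equal(respond_regular(99, p_sharp, seed = 1), "regular")

  # well-separated criteria: P(regular|x) ~ Phi((x-ce)/se) - Phi((x-cl)/sl)
  n <- 20000
  for (x in c(-100, -60, 0, 70, 120)) {
    analytic <- pnorm((x + 80) / 20) - pnorm((x - 80) / 20)
    mc <- mean(respond_regular(rep(x, n), p, seed = 42 + x) == "regular")
    expect_lt(abs(mc - analytic), 3 * sqrt(max(analytic * (1 - analytic), 1e-4) / n))
  }

  # lapses flip symmetric: P(regular|far outside) -> lapse rate
  p_lapse <- observer_params(criterion_sd_early = 1e-9, criterion_sd_late = 1e-9,
                             lapse_rate = 0.2)
  mc <- mean(respond_regular(rep(1000, n), p_lapse, seed = 9) == "regular")
  expect_lt(abs(mc - 0.2), 0.01)
})

test_that("temporal-order responses follow perceived times with light-first ties", {
  p0 <- observer_params(visual_latency_sd = 0, lapse_rate = 0)
  expect_equal(respond_toj(2800, 2900, p0, seed = 1), "sound_first")
  expect_equal(respond_toj(2800, 2700, p0, seed = 1), "light_first")
  expect_equal(respond_toj(2800, 2800, p0, seed = 1), "light_first")  # tie rule

  # P(light_first) increases with the light's lead time
  p <- observer_params(visual_latency_sd = 50, lapse_rate = 0.02)
  leads <- seq(-150, 150, by = 75)
  prob <- vapply(seq_along(leads), function(i) {
    mean(respond_toj(rep(2800, 20000), 2800 - leads[i], p,
                     seed = 100 + i) == "light_first")
  }, numeric(1))
  expect_true(all(diff(prob) > 0))
})

test_that("session simulation is a pure function of grid, params, and seed", {
  grid <- shuffle_grid(build_exp1_grid("regular", 1), seed = 2)
  p <- observer_params()
  a <- simulate_session(grid, p, seed = 10)
  b <- simulate_session(grid, p, seed = 10)
  expect_identical(a, b)
  expect_equal(nrow(a), 60)
  expect_true(all(a$response %in% c("regular", "irregular")))

  g2 <- shuffle_grid(build_exp2_grid("regular", 1), seed = 2)
  s2 <- simulate_session(g2, p, seed = 11)
  expect_true(all(s2$response %in% c("light_first", "sound_first")))
  expect_true(all(is.finite(s2$perceived_anisochrony_ms)))

  gp <- build_practice_grid(1)
  sp <- simulate_session(gp, p, seed = 12)
  expect_true(all(is.na(sp$perceived_anisochrony_ms)))
  expect_true(all(sp$response %in% c("light_first", "sound_first")))
})
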