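#' Bayesian observer parameters
#'
#' Parameter set for the simulated observer. The observer carries a
#' Gaussian prior over the onset time of the next tone, fuses it with a
#' Gaussian sensory likelihood at each tone (precision-weighted average),
#' and shifts the posterior forward by one inter-onset interval to form the
#' next prediction. Between tones the prediction loses precision at a rate
#' set by `interval_sd`, the observer's running estimate of how variable
#' the environment's intervals are; `env_learning_rate` controls how fast
#' that estimate tracks the root-mean-square prediction error across
#' trials.
#'
#' @param sensory_sd SD (ms) of the auditory sensory likelihood.
#' @param initial_prior_sd SD (ms) of the predicted-onset prior before any
#'   sequence evidence. Use a very large value for an (effectively) flat
#'   prior.
#' @param interval_sd per-step growth (ms) of prediction uncertainty — the
#'   environment-statistics parameter.
#' @param env_learning_rate exponential-smoothing rate in `[0, 1]` moving
#'   `interval_sd` toward the per-trial RMS prediction error; 0 disables
#'   learning.
#' @param criterion_early,criterion_late mean locations (ms) of the early
#'   (negative anisochrony) and late criteria of the regularity rule;
#'   `criterion_early < criterion_late`.
#' @param criterion_sd_early,criterion_sd_late trial-to-trial SDs (ms) of
#'   the two criteria.
#' @param visual_latency_sd SD (ms) of the flash's perceived-time noise in
#'   the temporal-order task.
#' @param lapse_rate probability in `[0, 0.5]` of flipping a response.
#' @return A list of class `observer_params`.
#' @export
#' @examples
#' p <- observer_params()
#' p$sensory_sd
observer_params <- function(sensory_sd = 25,
                            initial_prior_sd = 120,
                            interval_sd = 30,
                            env_learning_rate = 0,
                            criterion_early = -80,
                            criterion_late = 80,
                            criterion_sd_early = 25,
                            criterion_sd_late = 25,
                            visual_latency_sd = 50,
                            lapse_rate = 0.02) {
  params <- list(
    sensory_sd = sensory_sd, initial_prior_sd = initial_prior_sd,
    interval_sd = interval_sd, env_learning_rate = env_learning_rate,
    criterion_early = criterion_early, criterion_late = criterion_late,
    criterion_sd_early = criterion_sd_early,
    criterion_sd_late = criterion_sd_late,
    visual_latency_sd = visual_latency_sd, lapse_rate = lapse_rate
  )
  sds <- c("sensory_sd", "initial_prior_sd", "interval_sd",
           "criterion_sd_early", "criterion_sd_late", "visual_latency_sd")
  for (f in sds)
    if (params[[f]] < 0) stop(f, " must be >= 0")
  if (params$criterion_early >= params$criterion_late)
    stop("criterion_early must be < criterion_late")
  if (params$lapse_rate < 0 || params$lapse_rate > 0.5)
    stop("lapse_rate must lie in [0, 0.5]")
  if (params$env_learning_rate < 0 || params$env_learning_rate > 1)
    stop("env_learning_rate must lie in [0, 1]")
  class(params) <- "observer_params"
  params
}

#' Initialize the belief state at the first tone
#'
#' The prediction for the second tone is centered one interval estimate
#' after the (observed) first onset, with width `initial_prior_sd`.
#'
#' @param first_onset observed onset (ms) of the first tone.
#' @param params an [observer_params()] object.
#' @param ioi the observer's interval estimate (ms), fixed at the base IOI.
#' @return A list of class `belief_state`: `predicted_onset_mean`,
#'   `predicted_onset_sd`, `ioi_estimate`, `trials_seen`.
#' @export
init_belief <- function(first_onset, params, ioi = design_constants$ioi_ms) {
  state <- list(
    predicted_onset_mean = first_onset + ioi,
    predicted_onset_sd   = params$initial_prior_sd,
    ioi_estimate         = ioi,
    trials_seen          = 0L
  )
  class(state) <- "belief_state"
  state
}

#' Fuse the predicted-onset prior with a sensory observation
#'
#' Precision-weighted Gaussian fusion: the perceived onset is
#' `(m/sp^2 + x/ss^2) / (1/sp^2 + 1/ss^2)` and the posterior precision is
#' the sum of the prior and likelihood precisions. Degenerate widths are
#' handled as limits: a zero-SD component dominates (a noiseless
#' observation overrides the prior), while two infinitely wide components
#' carry no information and raise an error. The perceived onset always
#' lies between the prior mean and the observation.
#'
#' @param state a `belief_state`.
#' @param observed_onset the (noisy) observed onset in ms.
#' @param params an [observer_params()] object.
#' @return list with `perceived_onset` and `posterior_sd` (ms).
#' @export
fuse <- function(state, observed_onset, params) {
  sp <- state$predicted_onset_sd
  ss <- params$sensory_sd
  if (is.infinite(ss) && is.infinite(sp))
    stop("both prior and likelihood have zero precision: fusion undefined")
  # a noiseless observation overrides any prior (and vice versa)
  if (ss == 0) return(list(perceived_onset = observed_onset, posterior_sd = 0))
  if (sp == 0) return(list(perceived_onset = state$predicted_onset_mean,
                           posterior_sd = 0))
  wp <- 1 / sp^2   # Inf prior sd -> zero weight
  ws <- 1 / ss^2
  list(
    perceived_onset = (state$predicted_onset_mean * wp + observed_onset * ws) /
      (wp + ws),
    posterior_sd = sqrt(1 / (wp + ws))
  )
}

#' Advance the belief to the next tone
#'
#' The posterior, shifted forward by the interval estimate, becomes the
#' next prediction; its width grows by `interval_sd` in quadrature.
#'
#' @param state a `belief_state`.
#' @param posterior_mean,posterior_sd the fusion result (ms).
#' @param params an [observer_params()] object.
#' @return The updated `belief_state`.
#' @export
advance <- function(state, posterior_mean, posterior_sd, params) {
  state$predicted_onset_mean <- posterior_mean + state$ioi_estimate
  state$predicted_onset_sd   <- sqrt(posterior_sd^2 + params$interval_sd^2)
  state
}

# Run the init/fuse/advance recursion over a full tone sequence.
# Each observation is the physical onset plus sensory noise (drawn from the
# current RNG stream). Innovations are the pre-fusion prediction errors at
# tones 2..(n-1); the final (deviant) tone is excluded so the environment
# statistic tracks the sequence context, not the probe.
run_sequence_inference <- function(onsets, params, ioi = design_constants$ioi_ms) {
  n <- length(onsets)
  stopifnot(n >= 2)
  x1 <- onsets[1] + rnorm(1, 0, params$sensory_sd)
  state <- init_belief(x1, params, ioi)
  innovations <- numeric(0)
  if (n >= 3) {
    for (k in 2:(n - 1)) {
      xk <- onsets[k] + rnorm(1, 0, params$sensory_sd)
      innovations <- c(innovations, xk - state$predicted_onset_mean)
      f <- fuse(state, xk, params)
      state <- advance(state, f$perceived_onset, f$posterior_sd, params)
    }
  }
  xf <- onsets[n] + rnorm(1, 0, params$sensory_sd)
  pred_mean <- state$predicted_onset_mean
  pred_sd <- state$predicted_onset_sd
  f <- fuse(state, xf, params)
  list(
    perceived_onset = f$perceived_onset,
    posterior_sd = f$posterior_sd,
    predicted_onset_mean = pred_mean,
    predicted_onset_sd = pred_sd,
    perceived_anisochrony = f$perceived_onset - pred_mean,
    innovations = innovations
  )
}

#' Perceive the final tone of a sequence
#'
#' Runs the observer over tones 1..4 (each corrupted by sensory noise) and
#' fuses the final tone with the resulting prediction. The perceived
#' anisochrony is the perceived final onset minus the predicted onset; its
#' expectation is the physical anisochrony shrunk by
#' `w = sp^2 / (sp^2 + ss^2)` where `sp` is the prediction SD at the final
#' fusion (an informative prior pulls deviants toward the expected time).
#'
#' @param sequence a `stimulus_sequence` from [realize_sequence()].
#' @param params an [observer_params()] object.
#' @param seed optional integer seed (`NULL` draws from the current
#'   stream).
#' @return list with `perceived_anisochrony`, `perceived_onset`,
#'   `predicted_onset_mean`, `predicted_onset_sd`, `posterior_sd`,
#'   `innovations` (all ms).
#' @export
perceive_final <- function(sequence, params, seed = NULL) {
  stopifnot(length(sequence$tone_onsets_ms) >= 2)
  with_seed(seed,
            run_sequence_inference(sequence$tone_onsets_ms, params,
                                   ioi = design_constants$ioi_ms))
}

#' Prediction SD at the final fusion and the shrinkage weight
#'
#' Deterministic companions to [perceive_final()]: the prediction SD at
#' tone `n_tones` follows the same fuse/advance recursion regardless of
#' the data, so the shrinkage weight `w = sp^2/(sp^2 + ss^2)` is available
#' in closed form.
#'
#' @param params an [observer_params()] object.
#' @param n_tones sequence length (default 5).
#' @return `predicted_sd_at_final()`: the prior SD (ms) entering the final
#'   fusion. `shrinkage_weight()`: the multiplier in `[0, 1]` applied to
#'   the physical anisochrony in expectation.
#' @export
predicted_sd_at_final <- function(params, n_tones = 5) {
  sp <- params$initial_prior_sd
  if (n_tones >= 3) {
    for (k in 2:(n_tones - 1)) {
      post <- if (is.infinite(sp)) params$sensory_sd
              else sqrt(1 / (1 / sp^2 + 1 / params$sensory_sd^2))
      sp <- sqrt(post^2 + params$interval_sd^2)
    }
  }
  sp
}

#' @rdname predicted_sd_at_final
#' @export
shrinkage_weight <- function(params, n_tones = 5) {
  sp <- predicted_sd_at_final(params, n_tones)
  if (is.infinite(sp)) return(1)
  sp^2 / (sp^2 + params$sensory_sd^2)
}

#' Update the environment-statistics parameter
#'
#' Moves `interval_sd` toward the root-mean-square innovation (prediction
#' error) by exponential smoothing with rate `env_learning_rate`; rate 0
#' leaves the parameters unchanged.
#'
#' @param params an [observer_params()] object.
#' @param sequence_innovations numeric vector of prediction errors (ms)
#'   from one sequence.
#' @return The updated `observer_params`.
#' @export
update_environment <- function(params, sequence_innovations) {
  rate <- params$env_learning_rate
  if (rate == 0 || length(sequence_innovations) == 0) return(params)
  rms <- sqrt(mean(sequence_innovations^2))
  params$interval_sd <- (1 - rate) * params$interval_sd + rate * rms
  params
}

#' Two-noisy-criteria regularity response
#'
#' On each trial the early and late criteria are drawn from independent
#' Gaussians; the observer reports "regular" iff the perceived anisochrony
#' falls between them. A lapse flips the response with probability
#' `lapse_rate`. Vectorized over `perceived_anisochrony`.
#'
#' @param perceived_anisochrony perceived deviation(s) of the final tone
#'   (ms).
#' @param params an [observer_params()] object.
#' @param seed optional integer seed.
#' @return character vector, `"regular"` or `"irregular"`.
#' @export
respond_regular <- function(perceived_anisochrony, params, seed = NULL) {
  with_seed(seed, {
    n <- length(perceived_anisochrony)
    ce <- rnorm(n, params$criterion_early, params$criterion_sd_early)
    cl <- rnorm(n, params$criterion_late, params$criterion_sd_late)
    regular <- ce <= perceived_anisochrony & perceived_anisochrony <= cl
    flip <- runif(n) < params$lapse_rate
    ifelse(xor(regular, flip), "regular", "irregular")
  })
}

#' Temporal-order response: tone vs. flash
#'
#' The flash's perceived time is its onset plus zero-mean Gaussian latency
#' noise; the observer reports "light first" iff the perceived flash time
#' is at or before the perceived tone time (ties, a measure-zero event, go
#' to light-first by convention). A lapse flips the response. Vectorized.
#'
#' @param perceived_tone_onset perceived onset(s) of the tone (ms).
#' @param flash_onset physical flash onset(s) (ms).
#' @param params an [observer_params()] object.
#' @param seed optional integer seed.
#' @return character vector, `"light_first"` or `"sound_first"`.
#' @export
respond_toj <- function(perceived_tone_onset, flash_onset, params, seed = NULL) {
  with_seed(seed, {
    n <- max(length(perceived_tone_onset), length(flash_onset))
    perceived_flash <- flash_onset + rnorm(n, 0, params$visual_latency_sd)
    light_first <- perceived_flash <= perceived_tone_onset
    flip <- runif(n) < params$lapse_rate
    ifelse(xor(light_first, flip), "light_first", "sound_first")
  })
}

#' Simulate one session of an observer on a trial grid
#'
#' Realizes every trial, runs the observer, and records the 2AFC response:
#' regular/irregular for the regularity task, light-first/sound-first for
#' the temporal-order tasks. If `params$env_learning_rate > 0` the
#' observer's `interval_sd` is updated after each multi-tone trial from
#' that trial's prediction errors, so trial order matters (shuffle the grid
#' first). Practice trials (single tone + flash) involve no sequence prior
#' and no learning.
#'
#' @param grid a trial grid (typically from [shuffle_grid()]).
#' @param params an [observer_params()] object.
#' @param seed integer session seed; the whole table is a pure function of
#'   `(grid, params, seed)`.
#' @param ioi base inter-onset interval in ms.
#' @param observer_id identifier recorded in the output.
#' @return A tibble with one row per trial: `trial_id`, the condition
#'   columns, `perceived_anisochrony_ms` (`NA` for practice), `response`,
#'   `observer_id`, `seed`.
#' @export
simulate_session <- function(grid, params, seed, ioi = design_constants$ioi_ms,
                             observer_id = "obs1") {
  stopifnot(nrow(grid) > 0, inherits(params, "observer_params"))
  n <- nrow(grid)
  experiment <- grid$experiment
  jitter <- grid$jitter_level_ms
  aniso <- grid$anisochrony_ms
  soa <- grid$soa_ms
  perceived <- rep(NA_real_, n)
  response <- character(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      cond <- list(experiment = experiment[i], jitter_level_ms = jitter[i],
                   anisochrony_ms = aniso[i], soa_ms = soa[i])
      sq <- realize_sequence(cond, ioi = ioi, seed = NULL)
      if (experiment[i] == "practice") {
        tone_perceived <- sq$tone_onsets_ms[1] + rnorm(1, 0, params$sensory_sd)
        response[i] <- respond_toj(tone_perceived, sq$flash_onset_ms, params)
      } else {
        res <- run_sequence_inference(sq$tone_onsets_ms, params, ioi = ioi)
        perceived[i] <- res$perceived_anisochrony
        response[i] <- if (experiment[i] == "exp1") {
          respond_regular(res$perceived_anisochrony, params)
        } else {
          respond_toj(res$perceived_onset, sq$flash_onset_ms, params)
        }
        if (params$env_learning_rate > 0)
          params <- update_environment(params, res$innovations)
      }
    }
  })
  dplyr::bind_cols(
    tibble::tibble(trial_id = seq_len(n)),
    grid,
    tibble::tibble(perceived_anisochrony_ms = perceived,
                   response = response,
                   observer_id = observer_id,
                   seed = seed)
  )
}
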