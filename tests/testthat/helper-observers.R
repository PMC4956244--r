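# deterministic observer configurations used across tests

# no sensory/criterion/visual noise, flat prior: responses reflect physics
noiseless_flat_params <- function(...) {
  observer_params(sensory_sd = 0, initial_prior_sd = Inf, interval_sd = 0,
                  criterion_sd_early = 0, criterion_sd_late = 0,
                  visual_latency_sd = 0, lapse_rate = 0, ...)
}

# effectively flat prior with finite noise (null observer for cohort tests)
flat_prior_params <- function(...) {
  observer_params(initial_prior_sd = 1e6, interval_sd = 1e6,
                  env_learning_rate = 0, ...)
}

# one-row exp1/exp2 conditions without building a full grid
make_condition <- function(experiment = "exp1", jitter = 0, anisochrony = 0,
                           soa = NA_real_,
                           environment = "regular") {
  tibble::tibble(experiment = experiment, environment = environment,
                 jitter_level_ms = jitter, anisochrony_ms = anisochrony,
                 soa_ms = soa, repetition_index = 1L)
}

# closed-form prediction SD at the final fusion, written out independently
# of the package's recursion helpers
expected_final_prior_sd <- function(sp0, ss, v, n_tones = 5) {
  sp <- sp0
  for (k in seq_len(n_tones - 2)) {
    post_var <- 1 / (1 / sp^2 + 1 / ss^2)
    sp <- sqrt(post_var + v^2)
  }
  sp
}
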