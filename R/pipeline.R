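#' Cohort configuration
#'
#' Study-level settings for simulated cohorts: group size, repetitions,
#' the observer parameter distribution (means from [observer_params()],
#' between-observer SDs, truncated-Gaussian draws), Spearman-Karber
#' padding bounds, and the JND exclusion thresholds (above 250 ms in the
#' practice phase or 200 ms in the test phase, strict).
#'
#' @param n_observers_per_group observers per environment group.
#' @param ioi base inter-onset interval (ms).
#' @param exp1_repetitions,exp2_repetitions,practice_repetitions repeats
#'   per condition cell of the three grids.
#' @param observer_means an [observer_params()] object with the
#'   population-mean parameters.
#' @param observer_sds named numeric vector of between-observer SDs; names
#'   must be `observer_params` fields. Unnamed fields are held fixed.
#' @param practice_jnd_max,test_jnd_max exclusion thresholds (ms).
#' @param sk_bounds_test,sk_bounds_practice padding bounds (ms) for the
#'   Spearman-Karber estimator in the two phases (the practice SOAs reach
#'   +/-350 ms, so its pads are wider).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_observers_per_group = 12,
                          ioi = design_constants$ioi_ms,
                          exp1_repetitions = design_constants$exp1_repetitions,
                          exp2_repetitions = design_constants$exp2_repetitions,
                          practice_repetitions = design_constants$practice_repetitions,
                          observer_means = observer_params(env_learning_rate = 0.05),
                          observer_sds = c(sensory_sd = 5,
                                           initial_prior_sd = 20,
                                           interval_sd = 5,
                                           criterion_early = 10,
                                           criterion_late = 10,
                                           criterion_sd_early = 5,
                                           criterion_sd_late = 5,
                                           visual_latency_sd = 8),
                          practice_jnd_max = 250,
                          test_jnd_max = 200,
                          sk_bounds_test = c(-250, 250),
                          sk_bounds_practice = c(-400, 400)) {
  stopifnot(n_observers_per_group >= 1, practice_jnd_max > 0, test_jnd_max > 0,
            inherits(observer_means, "observer_params"))
  if (length(observer_sds) && is.null(names(observer_sds)))
    stop("observer_sds must be named")
  bad <- setdiff(names(observer_sds), names(unclass(observer_means)))
  if (length(bad)) stop("unknown observer_sds fields: ",
                        paste(bad, collapse = ", "))
  out <- list(
    n_observers_per_group = n_observers_per_group, ioi = ioi,
    exp1_repetitions = exp1_repetitions,
    exp2_repetitions = exp2_repetitions,
    practice_repetitions = practice_repetitions,
    observer_means = observer_means, observer_sds = observer_sds,
    practice_jnd_max = practice_jnd_max, test_jnd_max = test_jnd_max,
    sk_bounds_test = sk_bounds_test, sk_bounds_practice = sk_bounds_practice
  )
  class(out) <- "cohort_config"
  out
}

#' Draw one observer's parameters from the cohort distribution
#'
#' Gaussian draws around the population means for the fields named in
#' `observer_sds`, truncated to the parameter's valid range (SD-type
#' fields at a small positive floor; criteria re-drawn until ordered).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return An [observer_params()] object.
#' @export
draw_observer_params <- function(config, seed = NULL) {
  with_seed(seed, {
    means <- unclass(config$observer_means)
    sds <- config$observer_sds
    nonneg <- c("sensory_sd", "initial_prior_sd", "interval_sd",
                "criterion_sd_early", "criterion_sd_late",
                "visual_latency_sd")
    for (tries in 1:100) {
      draw <- means
      for (f in names(sds)) {
        v <- rnorm(1, means[[f]], sds[[f]])
        if (f %in% nonneg) v <- max(v, 1)
        if (f == "lapse_rate") v <- min(max(v, 0), 0.5)
        if (f == "env_learning_rate") v <- min(max(v, 0), 1)
        draw[[f]] <- v
      }
      if (draw$criterion_early < draw$criterion_late)
        return(do.call(observer_params, draw))
    }
    stop("could not draw ordered criteria after 100 tries")
  })
}

#' JND-based exclusion
#'
#' Applies the preregistered-style exclusion rule to a table of
#' Spearman-Karber estimates: rows with JND strictly above the phase's
#' threshold (250 ms practice, 200 ms test) are excluded; a JND exactly at
#' the threshold is retained. Row counts are conserved across the two
#' outputs.
#'
#' @param sk_estimates a tibble with columns `jnd_ms` and `phase`
#'   (`"practice"` or `"test"`).
#' @param config a [cohort_config()] providing the thresholds.
#' @return list with tibbles `retained` and `excluded`.
#' @export
apply_exclusion <- function(sk_estimates, config = cohort_config()) {
  if (!all(c("jnd_ms", "phase") %in% names(sk_estimates)))
    stop("sk_estimates must have columns jnd_ms and phase")
  if (nrow(sk_estimates) == 0)
    return(list(retained = sk_estimates, excluded = sk_estimates))
  threshold <- ifelse(sk_estimates$phase == "practice",
                      config$practice_jnd_max, config$test_jnd_max)
  drop <- sk_estimates$jnd_ms > threshold
  list(retained = sk_estimates[!drop, , drop = FALSE],
       excluded = sk_estimates[drop, , drop = FALSE])
}

#' Temporal regularisation index
#'
#' PSS difference between the late (+40 ms) and early (-40 ms) final-tone
#' deviants as a percentage of their physical separation. Under the
#' light-lead PSS convention (positive PSS = light must be presented
#' before sound), positive values mean the early/late separation is
#' perceptually compressed toward regularity; 100 is full regularisation,
#' 0 none.
#'
#' @param pss_early,pss_late PSS (ms) at the early and late anisochrony.
#' @param anisochrony_span physical early-to-late separation (ms), default
#'   80.
#' @return percentage(s).
#' @export
#' @examples
#' regularisation_index(-16, 16)  # 40
regularisation_index <- function(pss_early, pss_late, anisochrony_span = 80) {
  if (any(anisochrony_span <= 0)) stop("anisochrony_span must be > 0")
  100 * (pss_late - pss_early) / anisochrony_span
}

# simulate one group of observers on a grid builder; returns responses plus
# the per-observer parameter draws
simulate_group <- function(config, environment, build, master_seed,
                           group_label = environment) {
  n_obs <- config$n_observers_per_group
  seeds <- with_seed(master_seed, child_seeds(2 * n_obs))
  responses <- vector("list", n_obs)
  params_list <- vector("list", n_obs)
  for (i in seq_len(n_obs)) {
    obs_id <- sprintf("%s_%02d", group_label, i)
    params <- draw_observer_params(config, seed = seeds[i])
    params_list[[i]] <- params
    grid <- shuffle_grid(build(environment), seed = seeds[n_obs + i])
    responses[[i]] <- simulate_session(grid, params, seed = seeds[n_obs + i],
                                       ioi = config$ioi,
                                       observer_id = obs_id) |>
      dplyr::mutate(group = group_label, .before = 1)
  }
  list(responses = dplyr::bind_rows(responses),
       params = setNames(params_list,
                         sprintf("%s_%02d", group_label, seq_len(n_obs))))
}

#' Run the regularity-judgment experiment on simulated cohorts
#'
#' Simulates one regular-environment and one irregular-environment cohort
#' on the full jitter x anisochrony grid, then reproduces the analysis
#' surfaces: per-observer and group-level proportion-of-"regular" tables
#' (with the bounded probit transform), and per-observer two-criteria fits
#' on the 0-jitter sequences.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; the whole result is a pure function of
#'   `(config, seed)`.
#' @return list of tibbles: `responses`, `proportions` (per observer),
#'   `proportions_group` (4 x 15 rows per group, with `probit`),
#'   `fits` (one row per observer: criteria, sigmas, slopes, NLL).
#' @export
run_experiment1 <- function(config = cohort_config(), seed = 1) {
  seeds <- with_seed(seed, child_seeds(3))
  groups <- list(
    simulate_group(config, "regular",
                   function(env) build_exp1_grid(env, config$exp1_repetitions),
                   seeds[1]),
    simulate_group(config, "irregular",
                   function(env) build_exp1_grid(env, config$exp1_repetitions),
                   seeds[2])
  )
  responses <- dplyr::bind_rows(lapply(groups, `[[`, "responses"))
  proportions <- responses |>
    dplyr::group_by(.data$group, .data$observer_id, .data$jitter_level_ms,
                    .data$anisochrony_ms) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_regular = sum(.data$response == "regular"),
                     .groups = "drop") |>
    dplyr::mutate(p_regular = .data$n_regular / .data$n_trials)
  proportions$probit <- probit_bounded(proportions$p_regular)
  proportions_group <- proportions |>
    dplyr::group_by(.data$group, .data$jitter_level_ms,
                    .data$anisochrony_ms) |>
    dplyr::summarise(p_regular = mean(.data$p_regular), .groups = "drop")
  proportions_group$probit <- probit_bounded(proportions_group$p_regular)

  fit_seeds <- with_seed(seeds[3],
                         child_seeds(length(unique(proportions$observer_id))))
  zero_jitter <- proportions[proportions$jitter_level_ms == 0, ]
  obs_ids <- unique(zero_jitter$observer_id)
  fits <- vector("list", length(obs_ids))
  for (i in seq_along(obs_ids)) {
    sub <- zero_jitter[zero_jitter$observer_id == obs_ids[i], ]
    pd <- psychometric_data(sub$anisochrony_ms, sub$n_trials, sub$n_regular)
    f <- fit_two_criteria(pd, seed = fit_seeds[i])
    fits[[i]] <- tibble::tibble(
      group = sub$group[1], observer_id = obs_ids[i],
      c_early_ms = f$c_early_ms, c_late_ms = f$c_late_ms,
      sigma_early_ms = f$sigma_early_ms, sigma_late_ms = f$sigma_late_ms,
      slope_early = f$slope_early, slope_late = f$slope_late,
      nll = f$neg_log_likelihood, converged = f$converged
    )
  }
  list(responses = responses, proportions = proportions,
       proportions_group = proportions_group,
       fits = dplyr::bind_rows(fits))
}

#' Run the temporal-order experiment on simulated cohorts
#'
#' For each observer: a practice phase (single tone + flash, 11 SOAs) from
#' which a practice-phase PSS/JND is estimated; then the test phase
#' (five-tone sequences, +/-40 ms deviant, 9 SOAs). Observer-level test
#' JNDs come from the pooled test responses. The JND exclusion rule is
#' applied, per-cell (jitter x anisochrony) Spearman-Karber estimates are
#' computed for retained observers, and the regularisation index is
#' summarized per group and jitter level.
#'
#' All PSS values are on the light-lead axis (`light_lead_ms = -soa_ms`,
#' positive PSS = light must be presented before the sound), matching the
#' convention in which the index is positive under regularisation.
#'
#' @inheritParams run_experiment1
#' @return list: `responses` (test phase), `sk_observer` (practice and
#'   pooled test estimates per observer, with `phase`), `excluded`,
#'   `pss_cells` (per observer x jitter x anisochrony), `observer_index`
#'   (per-observer regularisation index per jitter), `regularisation`
#'   (group x jitter summary with `pss_early`, `pss_late`,
#'   `index_percent`), `jnd` (group x jitter mean JND).
#' @export
run_experiment2 <- function(config = cohort_config(), seed = 1) {
  seeds <- with_seed(seed, child_seeds(4))
  test_groups <- list(
    simulate_group(config, "regular",
                   function(env) build_exp2_grid(env, config$exp2_repetitions),
                   seeds[1]),
    simulate_group(config, "irregular",
                   function(env) build_exp2_grid(env, config$exp2_repetitions),
                   seeds[2])
  )
  # practice phase: same observers (same parameter seeds), no sequence
  practice <- vector("list", 2)
  for (g in 1:2) {
    grp <- test_groups[[g]]
    ids <- names(grp$params)
    pr_seeds <- with_seed(seeds[2 + g], child_seeds(length(ids)))
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      grid <- shuffle_grid(build_practice_grid(config$practice_repetitions),
                           seed = pr_seeds[i])
      rows[[i]] <- simulate_session(grid, grp$params[[i]], seed = pr_seeds[i],
                                    ioi = config$ioi, observer_id = ids[i]) |>
        dplyr::mutate(group = sub("_[0-9]+$", "", ids[i]), .before = 1)
    }
    practice[[g]] <- dplyr::bind_rows(rows)
  }
  practice <- dplyr::bind_rows(practice)
  responses <- dplyr::bind_rows(lapply(test_groups, `[[`, "responses"))
  practice$light_lead_ms <- -practice$soa_ms
  responses$light_lead_ms <- -responses$soa_ms

  per_observer_sk <- function(tbl, phase, bounds) {
    tbl |>
      dplyr::group_by(.data$group, .data$observer_id) |>
      dplyr::group_modify(~ sk_from_responses(.x, "light_lead_ms",
                                              "light_first",
                                              bounds[1], bounds[2])) |>
      dplyr::ungroup() |>
      dplyr::mutate(phase = phase)
  }
  sk_observer <- dplyr::bind_rows(
    per_observer_sk(practice, "practice", config$sk_bounds_practice),
    per_observer_sk(responses, "test", config$sk_bounds_test)
  )
  excl <- apply_exclusion(sk_observer, config)
  bad_ids <- unique(excl$excluded$observer_id)
  retained <- responses[!responses$observer_id %in% bad_ids, ]
  if (nrow(retained) == 0) {
    empty <- tibble::tibble(group = character(), observer_id = character(),
                            jitter_level_ms = numeric())
    return(list(responses = responses, sk_observer = sk_observer,
                excluded = excl$excluded,
                pss_cells = empty, observer_index = empty,
                regularisation = empty, jnd = empty))
  }

  pss_cells <- retained |>
    dplyr::group_by(.data$group, .data$observer_id, .data$jitter_level_ms,
                    .data$anisochrony_ms) |>
    dplyr::group_modify(~ sk_from_responses(.x, "light_lead_ms", "light_first",
                                            config$sk_bounds_test[1],
                                            config$sk_bounds_test[2])) |>
    dplyr::ungroup()

  observer_index <- pss_cells |>
    dplyr::select(dplyr::all_of(c("group", "observer_id", "jitter_level_ms",
                                  "anisochrony_ms", "pss_ms"))) |>
    tidyr::pivot_wider(names_from = "anisochrony_ms", values_from = "pss_ms",
                       names_prefix = "pss_") |>
    dplyr::rename(pss_early = "pss_-40", pss_late = "pss_40") |>
    dplyr::mutate(index_percent = regularisation_index(.data$pss_early,
                                                       .data$pss_late))
  regularisation <- observer_index |>
    dplyr::group_by(.data$group, .data$jitter_level_ms) |>
    dplyr::summarise(pss_early = mean(.data$pss_early),
                     pss_late = mean(.data$pss_late),
                     index_se = stats::sd(.data$index_percent) /
                       sqrt(dplyr::n()),
                     index_percent = mean(.data$index_percent),
                     n_observers = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("index_se", .after = "index_percent")
  jnd <- pss_cells |>
    dplyr::group_by(.data$group, .data$jitter_level_ms) |>
    dplyr::summarise(jnd_ms = mean(.data$jnd_ms), .groups = "drop")

  list(responses = responses, sk_observer = sk_observer,
       excluded = excl$excluded, pss_cells = pss_cells,
       observer_index = observer_index, regularisation = regularisation,
       jnd = jnd)
}

#' Write pipeline tables to CSV with a run log
#'
#' Writes every tibble in `tables` as `<name>.csv` under `outdir` (stable
#' column order as produced by the pipeline) plus a `run_log.txt`
#' recording the seed and configuration; reruns with the same inputs give
#' byte-identical files.
#'
#' @param tables named list of tibbles.
#' @param outdir output directory (created if needed).
#' @param seed the master seed used.
#' @param config the [cohort_config()] used.
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(tables, outdir, seed = NA, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tables <- tables[vapply(tables, is.data.frame, logical(1))]
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], path, na = "")
    paths <- c(paths, path)
  }
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(c(
    paste0("master_seed: ", seed),
    paste0("package_version: ", as.character(utils::packageVersion("tempreg"))),
    "config:",
    if (!is.null(config)) utils::capture.output(utils::str(config)) else "  (none)"
  ), log_path)
  invisible(c(paths, log_path))
}
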