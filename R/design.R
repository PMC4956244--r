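#' Trial-design constants
#'
#' Factor levels of the two experiments: base inter-onset interval (IOI),
#' per-environment jitter levels, final-tone anisochronies, and the
#' audiovisual SOA probes of the temporal-order task. Anisochrony is signed
#' (negative = final tone earlier than the regular grid); `soa` is the flash
#' onset minus the final tone onset.
#'
#' @format A named list.
#' @export
design_constants <- list(
  ioi_ms                = 700,
  jitter_levels         = list(regular = c(0, 10, 20, 30),
                               irregular = c(0, 50, 100, 150)),
  exp1_anisochronies    = c(0, -20, 20, -40, 40, -60, 60, -80, 80,
                            -100, 100, -150, 150, -200, 200),
  exp2_anisochronies    = c(-40, 40),
  exp2_soas             = c(0, -40, 40, -80, 80, -120, 120, -200, 200),
  practice_soas         = c(0, -20, 20, -90, 90, -170, 170, -250, 250,
                            -350, 350),
  exp1_repetitions      = 8,
  exp2_repetitions      = 10,
  practice_repetitions  = 6
)

jitter_levels_for <- function(environment) {
  environment <- match.arg(environment, c("regular", "irregular"))
  design_constants$jitter_levels[[environment]]
}

#' Build the regularity-judgment trial grid (Experiment 1)
#'
#' Full cross of the four environment-specific jitter levels, the 15 signed
#' final-tone anisochronies (0, +/-20, +/-40, +/-60, +/-80, +/-100, +/-150,
#' +/-200 ms) and `repetitions` repeats, in deterministic order (shuffle
#' separately with [shuffle_grid()]).
#'
#' @param environment `"regular"` (jitter levels 0/10/20/30 ms) or
#'   `"irregular"` (0/50/100/150 ms).
#' @param repetitions repeats per condition cell (the study design used 8).
#' @return A tibble with one row per trial condition: `experiment`,
#'   `environment`, `jitter_level_ms`, `anisochrony_ms`, `soa_ms` (always
#'   `NA` for this task), `repetition_index`.
#' @export
#' @examples
#' nrow(build_exp1_grid("regular", 8))  # 4 x 15 x 8 = 480
build_exp1_grid <- function(environment, repetitions = design_constants$exp1_repetitions) {
  stopifnot(is.numeric(repetitions), length(repetitions) == 1, repetitions >= 1)
  jit <- jitter_levels_for(environment)
  grid <- expand.grid(
    repetition_index = seq_len(repetitions),
    anisochrony_ms   = sort(design_constants$exp1_anisochronies),
    jitter_level_ms  = jit,
    KEEP.OUT.ATTRS = FALSE
  )
  tibble::tibble(
    experiment       = "exp1",
    environment      = environment,
    jitter_level_ms  = grid$jitter_level_ms,
    anisochrony_ms   = grid$anisochrony_ms,
    soa_ms           = NA_real_,
    repetition_index = grid$repetition_index
  )
}

#' Build the temporal-order trial grid (Experiment 2, test phase)
#'
#' Full cross of the four jitter levels, the two final-tone anisochronies
#' (+/-40 ms), nine audiovisual SOAs (0, +/-40, +/-80, +/-120, +/-200 ms)
#' and `repetitions` repeats. One quarter of the trials carry jitter level
#' 0 (the isochronous context).
#'
#' @inheritParams build_exp1_grid
#' @param repetitions repeats per condition cell (the study design used 10).
#' @return A tibble as in [build_exp1_grid()], with `soa_ms` filled in.
#' @export
build_exp2_grid <- function(environment, repetitions = design_constants$exp2_repetitions) {
  stopifnot(is.numeric(repetitions), length(repetitions) == 1, repetitions >= 1)
  jit <- jitter_levels_for(environment)
  grid <- expand.grid(
    repetition_index = seq_len(repetitions),
    soa_ms           = sort(design_constants$exp2_soas),
    anisochrony_ms   = design_constants$exp2_anisochronies,
    jitter_level_ms  = jit,
    KEEP.OUT.ATTRS = FALSE
  )
  tibble::tibble(
    experiment       = "exp2",
    environment      = environment,
    jitter_level_ms  = grid$jitter_level_ms,
    anisochrony_ms   = grid$anisochrony_ms,
    soa_ms           = grid$soa_ms,
    repetition_index = grid$repetition_index
  )
}

#' Build the practice-phase grid (single tone + flash temporal order)
#'
#' Eleven SOAs (0, +/-20, +/-90, +/-170, +/-250, +/-350 ms) crossed with
#' `repetitions` repeats. Practice trials have no tone sequence: a single
#' tone is paired with the flash.
#'
#' @param repetitions repeats per SOA (the study design used 6).
#' @return A tibble as in [build_exp1_grid()]; `jitter_level_ms` and
#'   `anisochrony_ms` are `NA`.
#' @export
build_practice_grid <- function(repetitions = design_constants$practice_repetitions) {
  stopifnot(is.numeric(repetitions), length(repetitions) == 1, repetitions >= 1)
  grid <- expand.grid(
    repetition_index = seq_len(repetitions),
    soa_ms           = sort(design_constants$practice_soas),
    KEEP.OUT.ATTRS = FALSE
  )
  tibble::tibble(
    experiment       = "practice",
    environment      = NA_character_,
    jitter_level_ms  = NA_real_,
    anisochrony_ms   = NA_real_,
    soa_ms           = grid$soa_ms,
    repetition_index = grid$repetition_index
  )
}

#' Shuffle a trial grid
#'
#' Random interleaving of conditions so the upcoming jitter level cannot be
#' anticipated; a seeded permutation of the rows (the multiset of
#' conditions is unchanged).
#'
#' @param grid a trial grid tibble.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return The permuted grid.
#' @export
shuffle_grid <- function(grid, seed = NULL) {
  with_seed(seed, grid[sample.int(nrow(grid)), , drop = FALSE])
}

#' Realize a trial condition into concrete stimulus onsets
#'
#' Tones 1-4 are laid out at the base IOI with an independent uniform
#' perturbation on `[-jitter, +jitter]` added to each of the three
#' intervals; the final tone sits on the *nominal* grid at
#' `4 * ioi + anisochrony` so that "expected" stays well defined under
#' jitter. The flash (if the condition has an SOA) follows the actual final
#' tone: `flash = final tone onset + soa`. Practice conditions produce a
#' single tone at 0 with the flash at `soa`.
#'
#' @param condition a one-row trial grid tibble (or a list with the same
#'   fields).
#' @param ioi base inter-onset interval in ms (default 700).
#' @param seed integer seed making the realization a pure function of
#'   `(condition, ioi, seed)`; `NULL` draws from the current stream.
#' @return A list of class `stimulus_sequence`: `tone_onsets_ms` (length 5,
#'   or 1 for practice), `flash_onset_ms` (`NA` if no flash), `condition`,
#'   `seed`.
#' @export
#' @examples
#' cond <- build_exp1_grid("regular", 1)[1, ]
#' realize_sequence(cond, seed = 1)$tone_onsets_ms
realize_sequence <- function(condition, ioi = design_constants$ioi_ms, seed = NULL) {
  cond <- as.list(condition)
  stopifnot(ioi > 0)
  if (identical(cond$experiment, "practice")) {
    out <- list(
      tone_onsets_ms = 0,
      flash_onset_ms = 0 + cond$soa_ms,
      condition = cond, seed = seed
    )
    class(out) <- "stimulus_sequence"
    return(out)
  }
  jitter <- cond$jitter_level_ms
  stopifnot(is.finite(jitter), jitter >= 0, jitter < ioi)
  onsets <- with_seed(seed, {
    perturb <- if (jitter > 0) runif(3, -jitter, jitter) else numeric(3)
    c(0, cumsum(ioi + perturb))
  })
  final <- 4 * ioi + cond$anisochrony_ms
  if (final <= onsets[4])
    stop("anisochrony/jitter combination yields non-increasing onsets")
  onsets <- c(onsets, final)
  flash <- if (is.na(cond$soa_ms)) NA_real_ else final + cond$soa_ms
  out <- list(tone_onsets_ms = onsets, flash_onset_ms = flash,
              condition = cond, seed = seed)
  class(out) <- "stimulus_sequence"
  out
}

#' Realize every trial in a grid and write/read trial tables
#'
#' `realize_grid()` turns a (typically shuffled) grid into a flat trial
#' table with one row per trial and the realized onsets as columns.
#'
#' @param grid a trial grid tibble.
#' @inheritParams realize_sequence
#' @param seed integer master seed; per-trial seeds are derived from it and
#'   recorded in the `seed` column.
#' @return A tibble with columns `trial_id`, the condition columns,
#'   `onset_1_ms` .. `onset_5_ms`, `flash_onset_ms`, `seed`.
#' @export
realize_grid <- function(grid, ioi = design_constants$ioi_ms, seed = 1L) {
  n <- nrow(grid)
  trial_seeds <- with_seed(seed, child_seeds(n))
  onsets <- matrix(NA_real_, n, 5)
  flash <- numeric(n)
  for (i in seq_len(n)) {
    sq <- realize_sequence(grid[i, ], ioi = ioi, seed = trial_seeds[i])
    onsets[i, seq_along(sq$tone_onsets_ms)] <- sq$tone_onsets_ms
    flash[i] <- sq$flash_onset_ms
  }
  colnames(onsets) <- paste0("onset_", 1:5, "_ms")
  dplyr::bind_cols(
    tibble::tibble(trial_id = seq_len(n)),
    grid,
    tibble::as_tibble(onsets),
    tibble::tibble(flash_onset_ms = flash, seed = trial_seeds)
  )
}

#' @rdname realize_grid
#' @param trials a realized trial table.
#' @param path file path for the CSV.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' @rdname realize_grid
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    experiment = readr::col_character(),
                    environment = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
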