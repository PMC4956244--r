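#' Per-level 2AFC counts
#'
#' Container for a psychometric data set: strictly increasing stimulus
#' levels with trial and positive-response counts.
#'
#' @param levels numeric vector of stimulus levels (ms), strictly
#'   increasing after sorting; at least 2.
#' @param n_trials,n_positive integer vectors, `0 <= n_positive <=
#'   n_trials`.
#' @return A tibble of class `psychometric_data` with columns `level_ms`,
#'   `n_trials`, `n_positive`, sorted by level.
#' @export
psychometric_data <- function(levels, n_trials, n_positive) {
  stopifnot(length(levels) >= 2,
            length(n_trials) == length(levels),
            length(n_positive) == length(levels))
  ord <- order(levels)
  levels <- levels[ord]; n_trials <- n_trials[ord]; n_positive <- n_positive[ord]
  if (anyDuplicated(levels)) stop("levels must be distinct")
  if (any(n_trials <= 0)) stop("n_trials must be positive")
  if (any(n_positive < 0 | n_positive > n_trials))
    stop("n_positive must lie in [0, n_trials]")
  out <- tibble::tibble(level_ms = levels, n_trials = n_trials,
                        n_positive = n_positive)
  class(out) <- c("psychometric_data", class(out))
  out
}

#' Aggregate a response table into per-level counts
#'
#' @param responses a response table (e.g. from [simulate_session()]).
#' @param level_col name of the numeric stimulus-level column.
#' @param positive the response value counted as "positive" (e.g.
#'   `"light_first"` or `"regular"`).
#' @param response_col name of the response column.
#' @return A [psychometric_data()] object; counts are conserved
#'   (`sum(n_trials) == nrow(responses)`).
#' @export
aggregate_responses <- function(responses, level_col, positive,
                                response_col = "response") {
  stopifnot(nrow(responses) > 0)
  if (!level_col %in% names(responses))
    stop("unknown level column: ", level_col)
  if (!response_col %in% names(responses))
    stop("unknown response column: ", response_col)
  agg <- responses |>
    dplyr::group_by(level_ms = .data[[level_col]]) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_positive = sum(.data[[response_col]] == positive),
      .groups = "drop"
    )
  psychometric_data(agg$level_ms, agg$n_trials, agg$n_positive)
}

# Weighted pooled-adjacent-violators: least-squares isotonic fit of y with
# weights w. Equal to stats::isoreg for unit weights; weights here are
# trial counts.
pava_weighted <- function(y, w) {
  n <- length(y)
  vals <- lapply(seq_len(n), function(k) list(v = y[k], w = w[k], ix = k))
  k <- 1
  while (k < length(vals)) {
    if (vals[[k]]$v > vals[[k + 1]]$v + 1e-12) {
      merged <- list(
        v = (vals[[k]]$v * vals[[k]]$w + vals[[k + 1]]$v * vals[[k + 1]]$w) /
          (vals[[k]]$w + vals[[k + 1]]$w),
        w = vals[[k]]$w + vals[[k + 1]]$w,
        ix = c(vals[[k]]$ix, vals[[k + 1]]$ix)
      )
      vals[[k]] <- merged
      vals[[k + 1]] <- NULL
      k <- max(1, k - 1)
    } else k <- k + 1
  }
  out <- numeric(n)
  for (b in vals) out[b$ix] <- b$v
  out
}

#' Spearman-Karber estimate of PSS and JND
#'
#' Non-parametric first and second moments of the discrete derivative of
#' the response-proportion curve. The level series is padded with
#' `(lower_bound, p = 0)` and `(upper_bound, p = 1)`; interval midpoints
#' `s_i = (L_{i+1} + L_i)/2` receive mass `dp_i = p_{i+1} - p_i`. The PSS
#' is the mass-weighted mean of the midpoints and the JND the square root
#' of the normalized second central moment (one SD of the underlying
#' distribution, i.e. the offset from the PSS reaching the .16/.84
#' proportions). Non-monotone proportions are first monotonized by
#' trial-count-weighted pooled-adjacent-violators and flagged.
#'
#' @param data a [psychometric_data()] object with the positive-response
#'   proportion *increasing* in the level.
#' @param lower_bound,upper_bound padding levels (ms) that must strictly
#'   bracket the observed levels; defaults +/-250.
#' @return A list of class `sk_estimate`: `pss_ms`, `jnd_ms`,
#'   `used_lower_bound`, `used_upper_bound`, `monotonized`.
#' @export
#' @examples
#' d <- psychometric_data(c(-100, 0, 100), rep(4, 3), c(0, 1, 4))
#' sk_estimate(d)  # PSS 25, JND sqrt(1875)
sk_estimate <- function(data, lower_bound = -250, upper_bound = 250) {
  stopifnot(inherits(data, "psychometric_data"))
  if (lower_bound >= min(data$level_ms) || upper_bound <= max(data$level_ms))
    stop("bounds must strictly bracket the levels")
  p <- data$n_positive / data$n_trials
  monotonized <- any(diff(c(0, p, 1)) < 0)
  if (monotonized)
    p <- pmin(pmax(pava_weighted(p, data$n_trials), 0), 1)
  lev <- c(lower_bound, data$level_ms, upper_bound)
  pp <- c(0, p, 1)
  s <- (lev[-1] + lev[-length(lev)]) / 2
  dp <- diff(pp)
  total <- sum(dp)          # equals 1 after padding; kept explicit
  pss <- sum(s * dp) / total
  jnd <- sqrt(sum(dp * (s - pss)^2) / total)
  out <- list(pss_ms = pss, jnd_ms = jnd,
              used_lower_bound = lower_bound,
              used_upper_bound = upper_bound,
              monotonized = monotonized)
  class(out) <- "sk_estimate"
  out
}

#' Spearman-Karber estimate straight from a response table
#'
#' Convenience wrapper: aggregate, estimate, return a one-row tibble.
#'
#' @inheritParams aggregate_responses
#' @inheritParams sk_estimate
#' @return One-row tibble: `pss_ms`, `jnd_ms`, `monotonized`, `n_trials`.
#' @export
sk_from_responses <- function(responses, level_col, positive,
                              lower_bound = -250, upper_bound = 250) {
  data <- aggregate_responses(responses, level_col, positive)
  est <- sk_estimate(data, lower_bound, upper_bound)
  tibble::tibble(pss_ms = est$pss_ms, jnd_ms = est$jnd_ms,
                 monotonized = est$monotonized,
                 n_trials = sum(data$n_trials))
}

#' Bounded probit transform of a proportion
#'
#' Clips the proportion into `[lower, upper]` and returns the standard
#' normal quantile, the transform used before level-by-level analysis of
#' regularity-response proportions.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param lower,upper clipping bounds, default .01/.99.
#' @return numeric vector of z-values.
#' @export
#' @examples
#' probit_bounded(c(0, 0.5, 1))
probit_bounded <- function(p, lower = 0.01, upper = 0.99) {
  if (lower >= upper) stop("lower must be < upper")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  qnorm(pmin(pmax(p, lower), upper))
}
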