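#' Two-noisy-criteria psychometric function
#'
#' Probability of a "regular" response as a function of final-tone
#' anisochrony under the two-noisy-criteria judgment model: the difference
#' of two cumulative Gaussians,
#' `Phi((x - c_early)/sigma_early) - Phi((x - c_late)/sigma_late)`,
#' clipped into `[0, 1]` (the difference form can dip below 0 when the
#' criteria overlap; for well-separated criteria it equals the exact
#' draw-two-criteria probability).
#'
#' @param x anisochrony value(s) in ms.
#' @param fit a list with `c_early_ms`, `c_late_ms`, `sigma_early_ms`,
#'   `sigma_late_ms` (e.g. a [two_criteria_fit()] or [fit_two_criteria()]
#'   result).
#' @return probabilities in `[0, 1]`.
#' @export
#' @examples
#' f <- two_criteria_fit(-60, 60, 20, 20)
#' predict_p_regular(0, f)
predict_p_regular <- function(x, fit) {
  p <- pnorm((x - fit$c_early_ms) / fit$sigma_early_ms) -
    pnorm((x - fit$c_late_ms) / fit$sigma_late_ms)
  pmin(pmax(p, 0), 1)
}

#' Construct a two-criteria parameter set
#'
#' @param c_early_ms,c_late_ms criterion locations (ms),
#'   `c_early_ms < c_late_ms`.
#' @param sigma_early_ms,sigma_late_ms positive slope parameters (ms); the
#'   density-at-threshold slopes `1/(sigma * sqrt(2*pi))` are derived.
#' @param neg_log_likelihood,converged,n_starts_used fit metadata.
#' @return A list of class `two_criteria_fit`.
#' @export
two_criteria_fit <- function(c_early_ms, c_late_ms, sigma_early_ms,
                             sigma_late_ms, neg_log_likelihood = NA_real_,
                             converged = NA, n_starts_used = NA_integer_) {
  if (!(c_early_ms < c_late_ms)) stop("c_early must be < c_late")
  if (sigma_early_ms <= 0 || sigma_late_ms <= 0) stop("sigmas must be > 0")
  out <- list(
    c_early_ms = c_early_ms, c_late_ms = c_late_ms,
    sigma_early_ms = sigma_early_ms, sigma_late_ms = sigma_late_ms,
    slope_early = 1 / (sigma_early_ms * sqrt(2 * pi)),
    slope_late = 1 / (sigma_late_ms * sqrt(2 * pi)),
    neg_log_likelihood = neg_log_likelihood,
    converged = converged, n_starts_used = n_starts_used
  )
  class(out) <- "two_criteria_fit"
  out
}

# Binomial negative log-likelihood; accepts fractional counts so analytic
# proportions can be fitted directly. Probabilities clipped to
# [1e-6, 1 - 1e-6] to guard the log.
two_criteria_nll <- function(ce, cl, se, sl, levels, n, k) {
  if (ce < -500 || cl > 500 || se < 1 || se > 500 || sl < 1 || sl > 500 ||
      ce >= cl)
    return(1e10)
  fit <- list(c_early_ms = ce, c_late_ms = cl,
              sigma_early_ms = se, sigma_late_ms = sl)
  q <- pmin(pmax(predict_p_regular(levels, fit), 1e-6), 1 - 1e-6)
  -sum(k * log(q) + (n - k) * log(1 - q))
}

# theta = (ce, log(cl - ce), log se, log sl): enforces order and positivity
theta_to_par <- function(theta) {
  theta <- unname(theta)
  ce <- theta[1]
  c(ce = ce, cl = ce + exp(theta[2]), se = exp(theta[3]), sl = exp(theta[4]))
}

# moment-based initial values: 0.5 crossings of the rising and falling
# branches, with quantile fallbacks for flat or noisy data
two_criteria_init <- function(levels, p) {
  imax <- which.max(p)
  rng <- range(levels)
  cross <- function(lv, pr) {
    if (length(lv) < 2 || max(pr) < 0.5 || min(pr) > 0.5) return(NA_real_)
    tryCatch(stats::approx(pr, lv, xout = 0.5, ties = mean)$y,
             error = function(e) NA_real_)
  }
  ce0 <- cross(levels[1:imax], p[1:imax])
  cl0 <- cross(rev(levels[imax:length(p)]), rev(p[imax:length(p)]))
  if (!is.finite(ce0)) ce0 <- rng[1] + 0.25 * diff(rng)
  if (!is.finite(cl0)) cl0 <- rng[1] + 0.75 * diff(rng)
  if (cl0 - ce0 < 1) { mid <- (ce0 + cl0) / 2; ce0 <- mid - 5; cl0 <- mid + 5 }
  s0 <- max(diff(rng) / 10, 5)
  c(ce0 = ce0, cl0 = cl0, s0 = s0)
}

#' Fit the two-noisy-criteria model by maximum likelihood
#'
#' Maximizes the binomial likelihood of the per-level "regular" counts
#' under [predict_p_regular()] with multi-start Nelder-Mead in a
#' transformed parameter space (criterion order and positive slopes are
#' enforced by construction; box constraints `sigma` in `[1, 500]` ms,
#' criteria within +/-500 ms), followed by a BFGS polish of the best
#' start.
#'
#' @param data a [psychometric_data()] object with at least 4 levels
#'   (`n_positive` counts the "regular" responses; fractional counts are
#'   accepted, so analytic proportions times a large `n_trials` can be fed
#'   directly).
#' @param n_starts number of jittered starting points (default 20).
#' @param seed integer seed for the start jitter.
#' @return A [two_criteria_fit()] with `neg_log_likelihood`, `converged`
#'   and `n_starts_used` filled in. All-positive or all-negative data are
#'   non-identifiable: the returned fit has `converged = FALSE` and a
#'   `diagnostic` message.
#' @export
fit_two_criteria <- function(data, n_starts = 20, seed = 1) {
  stopifnot(inherits(data, "psychometric_data"))
  levels <- data$level_ms; n <- data$n_trials; k <- data$n_positive
  if (length(levels) < 4)
    stop("at least 4 levels are required to fit 4 parameters")
  if (sum(k) == 0 || sum(k) == sum(n)) {
    fit <- two_criteria_fit(min(levels) - 1, max(levels) + 1, 100, 100,
                            converged = FALSE, n_starts_used = 0L)
    fit$diagnostic <- "non-identifiable: responses are constant across levels"
    return(fit)
  }
  obj <- function(theta) {
    par <- theta_to_par(theta)
    two_criteria_nll(par["ce"], par["cl"], par["se"], par["sl"], levels, n, k)
  }
  init <- two_criteria_init(levels, k / n)
  base <- c(init["ce0"], log(init["cl0"] - init["ce0"]),
            log(init["s0"]), log(init["s0"]))
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      theta0 <- if (s == 1) base else
        base + c(rnorm(1, 0, 20), rnorm(1, 0, 0.3), rnorm(2, 0, 0.5))
      opt <- tryCatch(
        optim(theta0, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
  })
  if (is.null(best)) stop("all optimizer starts failed")
  polish <- tryCatch(
    optim(best$par, obj, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  par <- theta_to_par(best$par)
  two_criteria_fit(
    c_early_ms = unname(par["ce"]), c_late_ms = unname(par["cl"]),
    sigma_early_ms = unname(par["se"]), sigma_late_ms = unname(par["sl"]),
    neg_log_likelihood = best$value,
    converged = best$convergence == 0,
    n_starts_used = as.integer(n_starts)
  )
}

#' Simulate binomial data from a two-criteria model
#'
#' @param fit a [two_criteria_fit()].
#' @param levels anisochrony levels (ms).
#' @param n_per_level trials per level (>= 1).
#' @param seed integer seed.
#' @return A [psychometric_data()] object.
#' @export
simulate_from_model <- function(fit, levels, n_per_level, seed = NULL) {
  stopifnot(n_per_level >= 1)
  p <- predict_p_regular(levels, fit)
  k <- with_seed(seed, rbinom(length(levels), n_per_level, p))
  psychometric_data(levels, rep(n_per_level, length(levels)), k)
}
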