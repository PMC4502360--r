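#' Bootstrap percentile confidence interval for the optimal response time
#'
#' For each response SD `sigma` on a grid, the expected-gain-maximising plan
#' `T*(sigma)` is computed, then sessions of `n_trials` Gaussian trials at
#' `(T*, sigma)` are simulated `n_replicates` times; each replicate is
#' summarised by its mean, the means are sorted ascending, and the 2.5% and
#' 97.5% points are taken as the 95% confidence interval of the optimal mean
#' response time. At `sigma = 0` every simulated trial equals `T*` and the
#' interval has zero width.
#'
#' Defaults follow the reference procedure: a 0-400 ms grid in 1-ms steps,
#' 3000 replicates of 100 trials. `sigmas` may equally be a handful of
#' participant-specific SDs. Replicate streams for each grid point are
#' derived deterministically from `seed` by a counter, so a subset of the
#' grid reproduces the same intervals as the full run.
#'
#' @param g A [gain_function()] or canonical condition label.
#' @param sigmas Numeric vector of response SDs (ms), all >= 0.
#' @param n_replicates Bootstrap replicates per grid point (>= 1).
#' @param n_trials Trials per simulated session (>= 1).
#' @param seed Optional integer seed; the global RNG state is left untouched.
#' @return A data frame of class `boot_ci` with columns `sigma`,
#'   `optimal_time`, `lower_95`, `upper_95`, and attributes `replicates`,
#'   `trials_per_replicate`, `gain_label`. Exportable as tabular text.
#' @export
#' @examples
#' bootstrap_ci(gain_risk_after(), sigmas = c(0, 100), n_replicates = 200,
#'              seed = 1)
bootstrap_ci <- function(g, sigmas = seq(0, 400, by = 1),
                         n_replicates = 3000, n_trials = 100, seed = NULL) {
  g <- as_gain(g)
  if (!is.numeric(sigmas) || !length(sigmas) || any(!is.finite(sigmas)) ||
      any(sigmas < 0))
    stop("`sigmas` must be finite and >= 0", call. = FALSE)
  if (n_replicates < 1 || n_trials < 1)
    stop("`n_replicates` and `n_trials` must be >= 1", call. = FALSE)
  one <- function(i) {
    s <- sigmas[i]
    tstar <- optimal_plan(g, s)$optimal_time
    if (s == 0) {
      means <- rep(tstar, n_replicates)
    } else {
      means <- with_seed_(derive_seed(seed, i), {
        rowMeans(matrix(stats::rnorm(n_replicates * n_trials, tstar, s),
                        nrow = n_replicates))
      })
    }
    means <- sort(means)
    b <- length(means)
    c(tstar,
      means[max(1L, floor(0.025 * b))],
      means[min(b, ceiling(0.975 * b))])
  }
  res <- vapply(seq_along(sigmas), one, numeric(3))
  structure(
    data.frame(sigma = sigmas, optimal_time = res[1, ],
               lower_95 = res[2, ], upper_95 = res[3, ]),
    replicates = n_replicates, trials_per_replicate = n_trials,
    gain_label = g$label, class = c("boot_ci", "data.frame"))
}

#' Empirical optimum by shifting the observed distribution
#'
#' Estimates the optimal mean response time directly from a measured sample:
#' the whole sample of response times is translated back and forth along the
#' time axis and the shift maximising the total gain
#' `sum_i G(t_i + s)` is selected. The optimal mean time is the observed
#' mean plus that shift. Ties are broken by the smallest `|s|`, then by the
#' negative shift. The raw sample (not a binned histogram) is shifted.
#'
#' @param times Numeric vector of observed response times (ms), outliers
#'   already removed; at least 2 values.
#' @param g A [gain_function()] or canonical condition label.
#' @param shift_min,shift_max,shift_step Shift grid (ms); defaults
#'   -1500 to 1500 in 1-ms steps.
#' @return A list of class `empirical_optimum`: `optimal_shift`,
#'   `optimal_mean_time`, `observed_mean_time`, `observed_total_gain`,
#'   `optimal_total_gain`.
#' @export
#' @examples
#' empirical_optimum(rep(2200, 10), gain_risk_after())$optimal_shift  # 100
empirical_optimum <- function(times, g, shift_min = -1500,
                              shift_max = 1500, shift_step = 1) {
  g <- as_gain(g)
  if (!length(times)) stop("empty sample", call. = FALSE)
  if (length(times) < 2) stop("need at least 2 trials", call. = FALSE)
  if (any(!is.finite(times))) stop("`times` must be finite", call. = FALSE)
  shifts <- seq(shift_min, shift_max, by = shift_step)
  total <- vapply(shifts, function(s) sum(gain_value(g, times + s)),
                  numeric(1))
  near <- which(total >= max(total) - 1e-9)
  s_star <- shifts[near][order(abs(shifts[near]), shifts[near])][1]
  structure(list(
    optimal_shift = s_star,
    optimal_mean_time = mean(times) + s_star,
    observed_mean_time = mean(times),
    observed_total_gain = sum(gain_value(g, times)),
    optimal_total_gain = max(total)),
    class = "empirical_optimum")
}

#' @export
print.empirical_optimum <- function(x, ...) {
  cat(sprintf(
    "<empirical_optimum: shift %+g ms -> optimal mean %.1f ms (observed %.1f), total gain %.0f -> %.0f>\n",
    x$optimal_shift, x$optimal_mean_time, x$observed_mean_time,
    x$observed_total_gain, x$optimal_total_gain))
  invisible(x)
}

#' Classify a participant's risk attitude
#'
#' Compares an observed mean response time with the 95% confidence interval
#' of the optimal mean time at the participant's response SD. A mean inside
#' the interval is risk-neutral. Under `risk_after` the penalty starts just
#' past the target, so a mean above the upper bound (closer to the target
#' than optimal) is risk-seeking and a mean below the lower bound is
#' risk-averse; under `risk_before` the geometry mirrors (below the lower
#' bound is risk-seeking).
#'
#' @param observed_mean Observed mean response time (ms).
#' @param ci Either a numeric length-2 vector `c(lower, upper)` (ms) or a
#'   [bootstrap_ci()] table, in which case `sigma` selects the row (nearest
#'   grid point within half a grid step; an error outside the grid range).
#' @param condition `"risk_after"` or `"risk_before"`.
#' @param sigma Participant response SD (ms); needed when `ci` is a table.
#' @return A list of class `risk_classification`: `label` (one of
#'   `"risk_neutral"`, `"risk_seeking"`, `"risk_averse"`), `observed_mean`,
#'   `ci` (lower, upper), `condition`.
#' @export
#' @examples
#' classify_strategy(2146, c(2000, 2060), "risk_after")$label  # risk_seeking
classify_strategy <- function(observed_mean, ci, condition, sigma = NULL) {
  if (!condition %in% c("risk_after", "risk_before"))
    stop("classification is defined for the asymmetric conditions only",
         call. = FALSE)
  if (inherits(ci, "boot_ci")) {
    if (is.null(sigma))
      stop("`sigma` is required to look up a bootstrap_ci table",
           call. = FALSE)
    step <- if (nrow(ci) > 1) min(diff(sort(ci$sigma))) else 1
    i <- which.min(abs(ci$sigma - sigma))
    if (abs(ci$sigma[i] - sigma) > step / 2 + 1e-9)
      stop(sprintf("sigma = %g ms is outside the CI grid", sigma),
           call. = FALSE)
    ci <- c(ci$lower_95[i], ci$upper_95[i])
  }
  if (!is.numeric(ci) || length(ci) != 2L || ci[1] > ci[2])
    stop("`ci` must be c(lower, upper) with lower <= upper", call. = FALSE)
  label <- if (observed_mean >= ci[1] && observed_mean <= ci[2]) {
    "risk_neutral"
  } else if (condition == "risk_after") {
    if (observed_mean > ci[2]) "risk_seeking" else "risk_averse"
  } else {
    if (observed_mean < ci[1]) "risk_seeking" else "risk_averse"
  }
  structure(list(label = label, observed_mean = observed_mean,
                 ci = c(lower = ci[[1]], upper = ci[[2]]),
                 condition = condition),
            class = "risk_classification")
}

#' @export
print.risk_classification <- function(x, ...) {
  cat(sprintf("<risk_classification: %s (mean %.1f ms vs CI [%.1f, %.1f], %s)>\n",
              x$label, x$observed_mean, x$ci[1], x$ci[2], x$condition))
  invisible(x)
}

# deterministic 32-bit sub-seed for stream `i`; NULL stays NULL (no seeding)
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1664525 * as.double(i)) %%
               2147483647)
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}
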