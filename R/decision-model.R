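#' Expected gain under Gaussian response uncertainty
#'
#' A planned response time `T` is executed with Gaussian motor noise: the
#' produced time `t` is distributed N(T, sigma^2). The expected gain of a
#' plan is the gain function integrated against that response distribution,
#'
#'   EG(T) = integral G(t) phi((t - T)/sigma) / sigma dt,
#'
#' computed here in closed form per linear segment. For a segment paying
#' `m t + c` on `(a, b]`, with `z = (bound - T)/sigma`,
#'
#'   E[(m t + c) 1(a < t <= b)] =
#'     m (T (Phi(z_b) - Phi(z_a)) - sigma (phi(z_b) - phi(z_a))) +
#'     c (Phi(z_b) - Phi(z_a)),
#'
#' summed over segments. Boundary membership is irrelevant under a
#' continuous density, so discontinuous gains integrate exactly. For
#' `sigma = 0` the density is degenerate and `EG(T) = G(T)`.
#'
#' @param g A [gain_function()] or canonical condition label.
#' @param planned_time Numeric vector of planned times `T` (ms).
#' @param sigma Response standard deviation (ms), a single value >= 0.
#' @return Numeric vector of expected gains (points), one per plan.
#' @export
#' @examples
#' expected_gain(gain_no_risk(), 2300, sigma = 100)   # ~96.53
#' expected_gain(gain_step(), 2300, sigma = 200)      # 100 (Phi(2) - Phi(-2))
expected_gain <- function(g, planned_time, sigma) {
  g <- as_gain(g)
  check_sigma(sigma)
  if (!is.numeric(planned_time) || any(!is.finite(planned_time)))
    stop("`planned_time` must be finite numeric", call. = FALSE)
  if (sigma == 0) return(gain_value(g, planned_time))
  lo <- c(-Inf, g$breaks)
  hi <- c(g$breaks, Inf)
  out <- numeric(length(planned_time))
  for (j in seq_along(g$slopes)) {
    za <- (lo[j] - planned_time) / sigma
    zb <- (hi[j] - planned_time) / sigma
    dPhi <- stats::pnorm(zb) - stats::pnorm(za)
    dphi <- stats::dnorm(zb) - stats::dnorm(za)
    out <- out + g$slopes[j] * (planned_time * dPhi - sigma * dphi) +
      g$intercepts[j] * dPhi
  }
  out
}

# analytic d EG / dT; for a segment (a, b] with payoff m t + c:
# d/dT = m (Phi(z_b) - Phi(z_a)) +
#        (m a + c) phi(z_a)/sigma - (m b + c) phi(z_b)/sigma
# (endpoint terms vanish at infinite bounds)
expected_gain_deriv <- function(g, planned_time, sigma) {
  lo <- c(-Inf, g$breaks)
  hi <- c(g$breaks, Inf)
  out <- numeric(length(planned_time))
  for (j in seq_along(g$slopes)) {
    za <- (lo[j] - planned_time) / sigma
    zb <- (hi[j] - planned_time) / sigma
    out <- out + g$slopes[j] * (stats::pnorm(zb) - stats::pnorm(za))
    if (is.finite(lo[j]))
      out <- out + (g$slopes[j] * lo[j] + g$intercepts[j]) *
        stats::dnorm(za) / sigma
    if (is.finite(hi[j]))
      out <- out - (g$slopes[j] * hi[j] + g$intercepts[j]) *
        stats::dnorm(zb) / sigma
  }
  out
}

#' Tabulate an expected-gain curve
#'
#' @inheritParams expected_gain
#' @param times Grid of planned times (ms); default spans
#'   `target +- (6 sigma + 500)` in 1-ms steps.
#' @return A data frame with columns `planned_time_ms`, `expected_gain`,
#'   writable as two-column tabular text.
#' @export
expected_gain_curve <- function(g, sigma, times = NULL) {
  g <- as_gain(g)
  check_sigma(sigma)
  if (is.null(times)) {
    half <- 6 * sigma + 500
    times <- g$target + seq(-half, half, by = 1)
  }
  data.frame(planned_time_ms = times,
             expected_gain = expected_gain(g, times, sigma))
}

#' Optimal planned response time
#'
#' Maximises expected gain over the planned time: a coarse 1-ms grid over
#' `target +- (6 sigma + 500)` locates the mode, then the root of the
#' analytic expected-gain derivative is polished to high precision
#' (golden-section refinement is used when the derivative carries no sign
#' change, e.g. on the flat plateau of the step gain at small sigma). Ties
#' within numerical tolerance are broken toward the target time, then toward
#' the smaller time — so for symmetric gains the optimum is exactly the
#' target. `sigma = 0` degenerates to the argmax of the gain itself.
#'
#' @inheritParams expected_gain
#' @param sigma Response SD (ms), >= 0.
#' @return An object of class `optimal_plan`: a list with `optimal_time`
#'   (ms), `optimal_expected_gain` (points, per trial), `session_gain`
#'   (points, the 100-trial session scale `100 * EG`), `sigma_used`, and
#'   `gain_label`.
#' @export
#' @examples
#' optimal_plan(gain_risk_after(), sigma = 150)  # ~2012.5 ms
#' optimal_plan(gain_no_risk(), sigma = 120)     # exactly 2300 ms
optimal_plan <- function(g, sigma) {
  g <- as_gain(g)
  check_sigma(sigma)
  if (sigma == 0) {
    tstar <- gain_argmax(g)
  } else {
    half <- 6 * sigma + 500
    grid <- g$target + seq(-half, half, by = 1)
    eg <- expected_gain(g, grid, sigma)
    near <- which(eg >= max(eg) - 1e-9)
    g0 <- grid[near][order(abs(grid[near] - g$target), grid[near])][1]
    dlo <- expected_gain_deriv(g, g0 - 1, sigma)
    dhi <- expected_gain_deriv(g, g0 + 1, sigma)
    tstar <- if (is.finite(dlo) && is.finite(dhi) && dlo > 0 && dhi < 0) {
      stats::uniroot(function(T) expected_gain_deriv(g, T, sigma),
                     c(g0 - 1, g0 + 1), tol = 1e-10)$root
    } else {
      golden_max(function(T) expected_gain(g, T, sigma),
                 g0 - 1, g0 + 1, tol = 1e-6)
    }
    # tie-break toward the target: symmetric gains return it exactly
    cand <- c(tstar, g$target, g0)
    ecand <- expected_gain(g, cand, sigma)
    keep <- ecand >= max(ecand) - 1e-9
    cand <- cand[keep]
    tstar <- cand[order(abs(cand - g$target), cand)][1]
  }
  eg_star <- expected_gain(g, tstar, sigma)
  structure(list(optimal_time = tstar,
                 optimal_expected_gain = eg_star,
                 session_gain = 100 * eg_star,
                 sigma_used = sigma,
                 gain_label = g$label),
            class = "optimal_plan")
}

#' @export
print.optimal_plan <- function(x, ...) {
  cat(sprintf(
    "<optimal_plan: %s, sigma = %g ms>\n  T* = %.2f ms, EG(T*) = %.3f points (%.1f per 100-trial session)\n",
    x$gain_label, x$sigma_used, x$optimal_time, x$optimal_expected_gain,
    x$session_gain))
  invisible(x)
}

# golden-section maximisation on [a, b] to absolute x tolerance
golden_max <- function(f, a, b, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Stationarity residual of the asymmetric-gain optimum
#'
#' For the `risk_after` gain the expected gain is
#' `EG(T) = (T Phi(z) - sigma phi(z)) / 23` with `z = (target - T)/sigma`,
#' so the first-order condition at the optimum reduces to
#' `Phi(z) = (target/sigma) phi(z)`. This function returns the residual
#' `Phi(z) - (target/sigma) phi(z)` (proportional to `dEG/dT`, so zero at
#' the true optimum and positive below it); for `risk_before` the mirrored,
#' sign-flipped expression — again proportional to that condition's own
#' `dEG/dT`. It serves as an analytic, optimiser-independent check on
#' [optimal_plan()].
#'
#' @param gain_label `"risk_after"` or `"risk_before"`.
#' @param planned_time Planned time `T` (ms).
#' @param sigma Response SD (ms), > 0.
#' @param target Target time (ms).
#' @return Dimensionless residual, vectorised over `planned_time`.
#' @export
stationarity_residual <- function(gain_label, planned_time, sigma,
                                  target = 2300) {
  if (!gain_label %in% c("risk_after", "risk_before"))
    stop("stationarity residual is defined for the asymmetric gains only",
         call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be > 0", call. = FALSE)
  sign <- 1
  if (gain_label == "risk_before") {
    planned_time <- 2 * target - planned_time
    sign <- -1
  }
  z <- (target - planned_time) / sigma
  sign * (stats::pnorm(z) - (target / sigma) * stats::dnorm(z))
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("`sigma` must be a single finite value >= 0", call. = FALSE)
  invisible(sigma)
}
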