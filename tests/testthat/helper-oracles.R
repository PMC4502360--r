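# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form path: expected gain by adaptive quadrature over the
# truncated Gaussian, optima by dense grid search.

# expected gain by stats::integrate, split at the gain's breakpoints so the
# quadrature never straddles a discontinuity
eg_quadrature <- function(g, planned_time, sigma) {
  stopifnot(sigma > 0)
  lo <- planned_time - 12 * sigma
  hi <- planned_time + 12 * sigma
  cuts <- sort(unique(c(lo, g$breaks[g$breaks > lo & g$breaks < hi], hi)))
  total <- 0
  for (j in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(
      function(t) gain_value(g, t) * stats::dnorm(t, planned_time, sigma),
      cuts[j], cuts[j + 1], rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  total
}

# optimum by brute-force dense grid (0.05-ms resolution near the mode)
tstar_grid <- function(g, sigma, half = NULL) {
  if (is.null(half)) half <- 6 * sigma + 500
  coarse <- seq(g$target - half, g$target + half, by = 1)
  v <- expected_gain(g, coarse, sigma)
  c0 <- coarse[which.max(v)]
  fine <- seq(c0 - 2, c0 + 2, by = 0.05)
  fine[which.max(expected_gain(g, fine, sigma))]
}

# random canonical gain / plan / sigma cases under a fixed seed
random_cases <- function(n, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      label = sample(c("no_risk", "step", "risk_after", "risk_before"),
                     n, replace = TRUE),
      planned_time = stats::runif(n, 1500, 3100),
      sigma = stats::runif(n, 10, 400))
  })
}
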