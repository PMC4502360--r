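#' Specify a synthetic timing agent
#'
#' An agent is a generative model of one participant: Gaussian motor noise
#' with SD `sigma` around a planned time, a planning policy, and lag-1
#' trial-by-trial dynamics.
#'
#' Policies:
#' * `"optimal"`: plans the expected-gain maximiser `T*(sigma)`.
#' * `"fixed_offset"`: plans `T*(sigma)` shifted `delta` ms toward the
#'   target time — the behavioral signature of risk seeking (positive
#'   `delta` moves the plan toward the zero-gain boundary).
#' * `"variance_misestimation"`: plans `T*(alpha * sigma)`, an agent who
#'   believes its noise is `alpha` times the true value (`alpha < 1`:
#'   overconfidence, which also pulls the plan toward the target under the
#'   asymmetric gains).
#'
#' Lag-1 dynamics: each trial is corrected back toward the plan by a
#' fraction `beta` of the previous trial's deviation, and a miss on the
#' previous trial triggers an extra `kappa` ms correction away from the
#' penalty region.
#'
#' @param sigma True response SD (ms), > 0.
#' @param policy One of `"optimal"`, `"fixed_offset"`,
#'   `"variance_misestimation"`.
#' @param delta Offset (ms) toward the target under `"fixed_offset"`.
#' @param alpha Multiplier on the believed SD under
#'   `"variance_misestimation"`, > 0.
#' @param beta Lag-1 compensation coefficient, `|beta| < 1` (stationarity).
#' @param kappa Extra post-miss correction (ms), >= 0.
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(sigma, policy = c("optimal", "fixed_offset",
                                         "variance_misestimation"),
                       delta = 0, alpha = 1, beta = 0, kappa = 0) {
  policy <- match.arg(policy)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0",
                                             call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (abs(beta) >= 1) stop("`beta` must satisfy |beta| < 1", call. = FALSE)
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, policy = policy, delta = delta,
                 alpha = alpha, beta = beta, kappa = kappa),
            class = "agent_spec")
}

#' Configure a simulated session
#'
#' @param condition Canonical condition label (one of `"no_risk"`,
#'   `"step"`, `"risk_after"`, `"risk_before"`).
#' @param n_trials Trials per session (default 100, the experimental
#'   session length).
#' @param target_time Target time (ms), default 2300.
#' @param foreperiods Candidate foreperiod durations (ms) sampled uniformly
#'   per trial; recorded in the log but without effect on response times,
#'   mirroring the task structure.
#' @return A list of class `session_config`.
#' @export
session_config <- function(condition, n_trials = 100, target_time = 2300,
                           foreperiods = seq(800, 1200, by = 100)) {
  if (!condition %in% canonical_labels)
    stop("`condition` must be one of ",
         paste(canonical_labels, collapse = ", "), call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  structure(list(condition = condition, n_trials = n_trials,
                 target_time = target_time, foreperiods = foreperiods),
            class = "session_config")
}

# direction in which risk seeking moves the plan (toward the target), and
# in which post-miss corrections must push (away from the penalty region):
# +1 under risk_after (penalty after the target), -1 under risk_before
risk_sign <- function(condition) {
  switch(condition, risk_after = 1, risk_before = -1, 0)
}

#' Planned response time of an agent
#'
#' @param agent An [agent_spec()].
#' @param g A [gain_function()] or canonical condition label.
#' @return Planned time (ms).
#' @export
plan_time <- function(agent, g) {
  stopifnot(inherits(agent, "agent_spec"))
  g <- as_gain(g)
  switch(agent$policy,
         optimal = optimal_plan(g, agent$sigma)$optimal_time,
         variance_misestimation =
           optimal_plan(g, agent$alpha * agent$sigma)$optimal_time,
         fixed_offset =
           optimal_plan(g, agent$sigma)$optimal_time +
           risk_sign(g$label) * agent$delta)
}

#' Simulate one session of trials
#'
#' Response times follow the agent's generative model:
#' `RT[1] = plan + e[1]` and
#' `RT[n+1] = plan - beta (RT[n] - plan) - s kappa 1(miss on n) + e[n+1]`,
#' with `e ~ N(0, sigma^2)` i.i.d. and `s` the unit direction pointing
#' toward the penalty region (so the `-s kappa` correction pushes away from
#' it). Misses are trials earning zero points under the session's gain
#' function. Simulated times are not clipped at zero; the analysis is
#' translation-based and the response model lives on the whole real line.
#'
#' @param agent An [agent_spec()].
#' @param cfg A [session_config()].
#' @param g Optional [gain_function()]; defaults to the canonical gain of
#'   `cfg$condition` at `cfg$target_time`.
#' @param participant_id Identifier written into the table.
#' @param seed Optional integer seed (global RNG state untouched).
#' @return A `trial_table` data frame (see [score_trials()]) with an extra
#'   `foreperiod_ms` column and attribute `agent` (the generating
#'   parameters, for recovery tests).
#' @export
simulate_session <- function(agent, cfg, g = NULL, participant_id = "S01",
                             seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"), inherits(cfg, "session_config"))
  if (is.null(g)) g <- as_gain(cfg$condition, target = cfg$target_time)
  plan <- plan_time(agent, g)
  s <- risk_sign(cfg$condition)
  n <- cfg$n_trials
  rt <- numeric(n)
  with_seed_(seed, {
    eps <- stats::rnorm(n, 0, agent$sigma)
    fp <- sample(cfg$foreperiods, n, replace = TRUE)
    rt[1] <- plan + eps[1]
    if (n > 1) for (i in seq_len(n - 1)) {
      missed <- gain_value(g, rt[i]) == 0
      rt[i + 1] <- plan - agent$beta * (rt[i] - plan) -
        s * agent$kappa * missed + eps[i + 1]
    }
    tab <- score_trials(rt, g, participant_id = participant_id,
                        condition = cfg$condition)
    tab$foreperiod_ms <- fp
    attr(tab, "agent") <- unclass(agent)
    attr(tab, "plan") <- plan
    tab
  })
}

#' Simulate a cohort of participants
#'
#' Draws each agent's true response SD from a log-normal distribution
#' (median `sigma_median`, log-scale SD `sigma_log_sd`), simulates one
#' session per agent under a shared policy, and returns the stacked trial
#' log in the standard format. The default spread (`sigma_log_sd = 0.3`)
#' keeps ~95% of SDs within roughly 70-240 ms around a 130-ms median, the
#' range spanned by measured participants. Deterministic given `seed`;
#' per-agent streams are derived by counter so cohorts of different sizes
#' share their leading agents.
#'
#' @param n_agents Number of agents (>= 1).
#' @param cfg A [session_config()].
#' @param policy,delta,alpha,beta,kappa Agent parameters shared by the
#'   cohort (see [agent_spec()]).
#' @param sigma_median Median of the SD distribution (ms), > 0.
#' @param sigma_log_sd SD of `log(sigma)`, >= 0.
#' @param seed Optional integer seed.
#' @return A `trial_table` with one session per agent (`participant_id`
#'   `"S01"`, `"S02"`, ...) and attribute `manifest`: a data frame of every
#'   agent's generating parameters (id, sigma, policy, delta, alpha, beta,
#'   kappa, plan) for parameter-recovery tests.
#' @export
simulate_cohort <- function(n_agents, cfg, policy = "optimal", delta = 0,
                            alpha = 1, beta = 0, kappa = 0,
                            sigma_median = 130, sigma_log_sd = 0.3,
                            seed = NULL) {
  if (n_agents < 1) stop("`n_agents` must be >= 1", call. = FALSE)
  if (!is.numeric(sigma_median) || sigma_median <= 0 ||
      !is.numeric(sigma_log_sd) || sigma_log_sd < 0)
    stop("invalid sigma distribution parameters", call. = FALSE)
  stopifnot(inherits(cfg, "session_config"))
  sigmas <- with_seed_(derive_seed(seed, 0), {
    stats::rlnorm(n_agents, meanlog = log(sigma_median),
                  sdlog = sigma_log_sd)
  })
  ids <- sprintf("S%02d", seq_len(n_agents))
  sessions <- vector("list", n_agents)
  plans <- numeric(n_agents)
  for (i in seq_len(n_agents)) {
    ag <- agent_spec(sigmas[i], policy = policy, delta = delta,
                     alpha = alpha, beta = beta, kappa = kappa)
    sessions[[i]] <- simulate_session(ag, cfg, participant_id = ids[i],
                                      seed = derive_seed(seed, i))
    plans[i] <- attr(sessions[[i]], "plan")
  }
  out <- do.call(rbind, lapply(sessions, as.data.frame))
  manifest <- data.frame(participant_id = ids, sigma = sigmas,
                         policy = policy, delta = delta, alpha = alpha,
                         beta = beta, kappa = kappa, plan = plans,
                         condition = cfg$condition)
  structure(out, manifest = manifest,
            class = c("trial_table", "data.frame"))
}
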