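#' Build a run configuration
#'
#' One flat configuration drives a full analysis run: either a path to a
#' trial log or a simulation block, plus the settings of every stochastic
#' or tunable stage. Every stage derives its stream deterministically from
#' the top-level `seed`, so identical configurations give byte-identical
#' tabular outputs.
#'
#' @param input Path to a trial-log CSV (see [read_trial_log()]), or `NULL`
#'   when `simulation` is given.
#' @param simulation Named list passed to [simulate_cohort()] (fields:
#'   `n_agents`, `condition`, and optionally `n_trials`, `policy`, `delta`,
#'   `alpha`, `beta`, `kappa`, `sigma_median`, `sigma_log_sd`).
#' @param conditions Conditions to analyse; default: all present in the
#'   data.
#' @param bootstrap List: `n_replicates` (default 3000), `n_trials`
#'   (default 100).
#' @param shift List: `min`, `max`, `step` for [empirical_optimum()]
#'   (defaults -1500, 1500, 1).
#' @param outlier_threshold SD multiplier for [flag_outliers()] (default
#'   2.5).
#' @param bin_convention `"exp1"` or `"exp2"` for [compensation_table()].
#' @param seed Top-level integer seed.
#' @param out_dir Optional output directory; when given, [run_pipeline()]
#'   writes the report tables and a manifest there as plain text.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulation = NULL, conditions = NULL,
                       bootstrap = list(), shift = list(),
                       outlier_threshold = 2.5,
                       bin_convention = c("exp1", "exp2"),
                       seed = 1L, out_dir = NULL) {
  bin_convention <- match.arg(bin_convention)
  if (is.null(input) && is.null(simulation))
    stop("config needs `input` or a `simulation` block", call. = FALSE)
  boot <- utils::modifyList(list(n_replicates = 3000, n_trials = 100),
                            bootstrap)
  sh <- utils::modifyList(list(min = -1500, max = 1500, step = 1), shift)
  if (!is.numeric(outlier_threshold) || outlier_threshold <= 0)
    stop("config field `outlier_threshold` must be > 0", call. = FALSE)
  structure(list(input = input, simulation = simulation,
                 conditions = conditions, bootstrap = boot, shift = sh,
                 outlier_threshold = outlier_threshold,
                 bin_convention = bin_convention, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, x)
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a trial log, then per participant and condition:
#' flags outliers, scores gains, estimates the response SD and mean from
#' non-outlier trials, computes the model optimum [optimal_plan()] and the
#' distribution-shift optimum [empirical_optimum()], bootstraps the 95% CI
#' of the optimal mean time at the participant's SD, classifies the risk
#' attitude (asymmetric conditions), runs the M-binned compensation
#' analysis (applying each participant's risk-condition M also to their
#' no-risk session, when present) and the split-half learning check.
#'
#' @param cfg A [run_config()] (or path to a YAML file for one).
#' @return A list of class `pipeline_report`:
#' \describe{
#'   \item{participants}{per participant-condition summary: n trials,
#'     outliers, observed mean/SD, observed total gain, model optimal time
#'     and session gain, empirical optimal mean/shift/total gain, CI bounds
#'     and risk label.}
#'   \item{table1}{per-condition summary in the optimal-vs-observed layout
#'     (see [compare_table1()]).}
#'   \item{compensation}{per participant-condition-bin mean compensation.}
#'   \item{split_half}{per-condition learning check.}
#'   \item{trials}{the scored trial table (all trials, with flags).}
#'   \item{manifest}{configuration echo, seed, package version, and the
#'     simulation manifest when simulated.}
#' }
#' When `cfg$out_dir` is set the tables are also written there as CSV plus
#' a YAML manifest.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  trials <- pipeline_input(cfg)
  conds <- cfg$conditions
  if (is.null(conds)) conds <- unique(trials$condition)
  trials <- trials[trials$condition %in% conds, , drop = FALSE]
  scored <- score_sessions(trials, cfg$outlier_threshold)
  participants <- analyze_participants(scored, cfg)
  comp <- compensation_report(scored, participants, cfg)
  sh <- lapply(split(scored, scored$condition), split_half_quiet)
  report <- structure(list(
    participants = participants,
    table1 = compare_table1(participants),
    compensation = comp,
    split_half = sh,
    trials = scored,
    manifest = pipeline_manifest(cfg, trials)),
    class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# --- pipeline stages -------------------------------------------------------

pipeline_input <- function(cfg) {
  if (!is.null(cfg$input)) {
    if (!file.exists(cfg$input))
      stop("input not readable: ", cfg$input, call. = FALSE)
    return(read_trial_log(cfg$input))
  }
  sim <- cfg$simulation
  need <- c("n_agents", "condition")
  miss <- setdiff(need, names(sim))
  if (length(miss))
    stop("config field simulation.", miss[1], " is required", call. = FALSE)
  scfg <- session_config(sim$condition,
                         n_trials = sim$n_trials %||% 100)
  if (scfg$n_trials != 100)
    warning("simulation.n_trials != 100; analyses assume 100-trial sessions",
            call. = FALSE)
  args <- sim[intersect(names(sim), c("policy", "delta", "alpha", "beta",
                                      "kappa", "sigma_median",
                                      "sigma_log_sd"))]
  do.call(simulate_cohort,
          c(list(n_agents = sim$n_agents, cfg = scfg,
                 seed = derive_seed(cfg$seed, 1000L)), args))
}

# re-score every session so outlier flags and gains are consistent with the
# configured threshold, whatever the input source
score_sessions <- function(trials, threshold) {
  parts <- split(trials,
                 list(trials$participant_id, trials$condition), drop = TRUE)
  scored <- lapply(parts, function(s) {
    s <- s[order(s$trial_index), ]
    tab <- score_trials(s$response_time_ms, as_gain(s$condition[1]),
                        participant_id = s$participant_id[1],
                        condition = s$condition[1],
                        outlier_threshold = threshold)
    tab$trial_index <- s$trial_index
    if (!is.null(s$foreperiod_ms)) tab$foreperiod_ms <- s$foreperiod_ms
    tab
  })
  out <- do.call(rbind, scored)
  rownames(out) <- NULL
  attr(out, "manifest") <- attr(trials, "manifest")
  structure(out, class = c("trial_table", "data.frame"))
}

analyze_participants <- function(scored, cfg) {
  groups <- split(scored,
                  list(scored$participant_id, scored$condition), drop = TRUE)
  rows <- lapply(seq_along(groups), function(k) {
    s <- groups[[k]]
    cond <- s$condition[1]
    g <- as_gain(cond)
    keep <- s$response_time_ms[!s$outlier]
    obs_mean <- mean(keep)
    obs_sd <- stats::sd(keep)
    plan <- optimal_plan(g, obs_sd)
    emp <- empirical_optimum(keep, g, cfg$shift$min, cfg$shift$max,
                             cfg$shift$step)
    row <- data.frame(
      participant_id = s$participant_id[1], condition = cond,
      n_trials = nrow(s), n_outliers = sum(s$outlier),
      observed_mean = obs_mean, observed_sd = obs_sd,
      observed_total_gain = sum(s$gain),
      optimal_time = plan$optimal_time,
      optimal_total_gain = plan$session_gain,
      empirical_optimal_mean = emp$optimal_mean_time,
      optimal_shift = emp$optimal_shift,
      shifted_total_gain = emp$optimal_total_gain,
      ci_lower = NA_real_, ci_upper = NA_real_,
      risk_label = NA_character_)
    if (cond %in% c("risk_after", "risk_before")) {
      ci <- bootstrap_ci(g, sigmas = obs_sd,
                         n_replicates = cfg$bootstrap$n_replicates,
                         n_trials = cfg$bootstrap$n_trials,
                         seed = derive_seed(cfg$seed, 2000L + k))
      row$ci_lower <- ci$lower_95
      row$ci_upper <- ci$upper_95
      row$risk_label <- classify_strategy(
        obs_mean, c(ci$lower_95, ci$upper_95), cond)$label
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$condition, out$participant_id), ]
}

compensation_report <- function(scored, participants, cfg) {
  risk <- participants[participants$condition %in%
                         c("risk_after", "risk_before"), ]
  M_by_id <- stats::setNames(abs(risk$observed_mean - 2300),
                             risk$participant_id)
  groups <- split(scored,
                  list(scored$participant_id, scored$condition), drop = TRUE)
  rows <- lapply(groups, function(s) {
    id <- s$participant_id[1]
    if (!id %in% names(M_by_id)) return(NULL)   # no risk-condition M
    M <- M_by_id[[id]]
    if (M <= 0) return(NULL)
    ct <- compensation_table(s, M, cfg$bin_convention)
    cbind(participant_id = id, condition = s$condition[1],
          as.data.frame(ct), M = M)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

split_half_quiet <- function(s) {
  withCallingHandlers(split_half_check(s),
                      warning = function(w) invokeRestart("muffleWarning"))
}

#' Per-condition optimal-vs-observed summary
#'
#' Condenses a per-participant table into the standard layout: per
#' condition, mean +- SD of the model optimal time, observed mean time,
#' optimal session gain (`100 x EG(T*)`) and observed total gain, with the
#' paired t and Cohen's d for the optimal-observed contrasts. Statistics
#' are suppressed (`NA`) for a single participant or degenerate contrasts.
#'
#' @param participants The per-participant table of a [run_pipeline()]
#'   report (or any data frame with its columns).
#' @return A data frame, one row per condition.
#' @export
compare_table1 <- function(participants) {
  rows <- lapply(split(participants, participants$condition), function(p) {
    n <- nrow(p)
    st_time <- try_paired(p$optimal_time, p$observed_mean)
    st_gain <- try_paired(p$optimal_total_gain, p$observed_total_gain)
    data.frame(
      condition = p$condition[1], n = n,
      optimal_time_mean = mean(p$optimal_time),
      optimal_time_sd = if (n > 1) stats::sd(p$optimal_time) else NA_real_,
      observed_time_mean = mean(p$observed_mean),
      observed_time_sd = if (n > 1) stats::sd(p$observed_mean) else NA_real_,
      time_t = st_time$t, time_df = st_time$df, time_p = st_time$p,
      time_d = st_time$cohen_d,
      optimal_gain_mean = mean(p$optimal_total_gain),
      optimal_gain_sd = if (n > 1) stats::sd(p$optimal_total_gain)
                        else NA_real_,
      observed_gain_mean = mean(p$observed_total_gain),
      observed_gain_sd = if (n > 1) stats::sd(p$observed_total_gain)
                         else NA_real_,
      gain_t = st_gain$t, gain_df = st_gain$df, gain_p = st_gain$p,
      gain_d = st_gain$cohen_d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

try_paired <- function(a, b) {
  res <- try(paired_stats(a, b), silent = TRUE)
  if (inherits(res, "try-error"))
    list(t = NA_real_, df = NA_real_, p = NA_real_, cohen_d = NA_real_)
  else res
}

pipeline_manifest <- function(cfg, trials) {
  list(seed = cfg$seed,
       outlier_threshold = cfg$outlier_threshold,
       bin_convention = cfg$bin_convention,
       bootstrap = cfg$bootstrap,
       shift = cfg$shift,
       input = cfg$input %||% "simulated",
       simulation = cfg$simulation,
       package_version = as.character(utils::packageVersion("riskytiming")),
       simulation_manifest = attr(trials, "manifest"))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE)
  }
  wr(report$participants, "participants.csv")
  wr(report$table1, "table1.csv")
  wr(report$compensation, "compensation.csv")
  wr(report$trials, "trials.csv")
  sh <- do.call(rbind, lapply(names(report$split_half), function(cd)
    cbind(condition = cd, report$split_half[[cd]]$per_participant)))
  wr(sh, "split_half.csv")
  man <- report$manifest
  man$simulation_manifest <- if (!is.null(man$simulation_manifest))
    lapply(as.list(man$simulation_manifest), as.vector)
  yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  participants: %d rows over %s\n",
              nrow(x$participants),
              paste(unique(x$participants$condition), collapse = ", ")))
  cat("  table1:\n")
  print(x$table1[, c("condition", "n", "optimal_time_mean",
                     "observed_time_mean", "optimal_gain_mean",
                     "observed_gain_mean")], row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
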