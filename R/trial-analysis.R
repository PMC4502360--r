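#' Flag response-time outliers
#'
#' Single-pass rule: trials whose response time lies more than
#' `threshold` standard deviations from the mean of all trials in the same
#' participant-by-condition session are flagged and excluded from every
#' downstream time statistic. The mean and SD are computed once, over all
#' trials (no iterative re-flagging). A session of identical times has
#' SD 0 and flags nothing.
#'
#' @param times Numeric vector of response times (ms), at least 3 trials.
#' @param threshold SD multiplier; default 2.5.
#' @return Logical vector, `TRUE` for outliers.
#' @export
flag_outliers <- function(times, threshold = 2.5) {
  if (length(times) < 3)
    stop("need at least 3 trials to flag outliers", call. = FALSE)
  if (any(!is.finite(times))) stop("`times` must be finite", call. = FALSE)
  s <- stats::sd(times)
  if (s == 0) return(rep(FALSE, length(times)))
  abs(times - mean(times)) > threshold * s
}

#' Score a session of trials against a gain function
#'
#' Builds the standard per-trial table: each response time earns
#' `gain_value(g, t)` points, a miss is a trial earning exactly zero points,
#' and outliers are flagged by [flag_outliers()]. Under the no-risk gain
#' every trial in the plausible range is a success; under the asymmetric
#' gains every response on the penalty side of the target is a miss.
#'
#' @param times Numeric vector of response times (ms), in trial order.
#' @param g A [gain_function()] or canonical condition label.
#' @param participant_id Participant identifier.
#' @param condition Condition label recorded in the table; defaults to the
#'   gain function's label.
#' @param outlier_threshold SD multiplier passed to [flag_outliers()].
#' @return A `trial_table` data frame with columns `participant_id`,
#'   `condition`, `trial_index`, `response_time_ms`, `gain`, `miss`,
#'   `outlier`.
#' @export
score_trials <- function(times, g, participant_id = "P01",
                         condition = NULL, outlier_threshold = 2.5) {
  g <- as_gain(g)
  gains <- gain_value(g, times)
  structure(
    data.frame(
      participant_id = participant_id,
      condition = if (is.null(condition)) g$label else condition,
      trial_index = seq_along(times),
      response_time_ms = as.numeric(times),
      gain = gains,
      miss = gains == 0,
      outlier = flag_outliers(times, outlier_threshold)),
    class = c("trial_table", "data.frame"))
}

#' Per-participant distance of the mean from the target
#'
#' `M = |mean RT - target|`, the absolute distance between a session's mean
#' response time (outliers excluded) and the target time. M scales the
#' error bins of the compensation analysis so data from participants with
#' different distances to the penalty boundary are comparable.
#'
#' @param times Response times (ms) of one session.
#' @param outlier Optional logical flags; flagged trials are excluded.
#' @param target Target time (ms).
#' @return M in ms.
#' @export
#' @examples
#' m_statistic(rep(2146.2, 5))  # 153.8
m_statistic <- function(times, outlier = NULL, target = 2300) {
  if (!is.null(outlier)) times <- times[!outlier]
  if (!length(times)) stop("no non-outlier trials", call. = FALSE)
  abs(mean(times) - target)
}

#' Trial-by-trial compensation by M-scaled error bins
#'
#' The compensation on trial `n` is the change to the next trial,
#' `RT[n+1] - RT[n]`. Each trial's response error is its deviation from the
#' session's (post-exclusion) mean, `error[n] = RT[n] - mean(RT)`, and
#' trials are sorted into four bins on the error axis with edges
#' `{-2M, -M, 0, M, 2M}`. Two published edge conventions are supported:
#' `"exp1"` uses left-open/right-closed intervals (errors `<= -2M` or
#' `> 2M` excluded), `"exp2"` left-closed/right-open (errors `< -2M` or
#' `>= 2M` excluded). Pairs where either trial is an outlier, and the final
#' trial (no successor), are dropped.
#'
#' @param table A `trial_table` (one participant-condition session, ordered
#'   by `trial_index`), or a numeric vector of response times.
#' @param M Bin scale (ms), > 0; typically [m_statistic()] of the
#'   participant's risk-condition session.
#' @param convention `"exp1"` or `"exp2"` bin-edge convention.
#' @return A `compensation_table` data frame: one row per bin with `bin`,
#'   `lower`, `upper` (in ms, derived from M), `n_pairs`,
#'   `mean_compensation` (ms; `NA` for an empty bin); attribute `M`.
#' @export
compensation_table <- function(table, M, convention = c("exp1", "exp2")) {
  convention <- match.arg(convention)
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0)
    stop("`M` must be a single value > 0", call. = FALSE)
  if (is.numeric(table))
    table <- data.frame(response_time_ms = table,
                        outlier = rep(FALSE, length(table)))
  rt <- table$response_time_ms
  out <- table$outlier
  if (length(rt) < 2) stop("need at least 2 trials", call. = FALSE)
  keep_rt <- rt[!out]
  if (!length(keep_rt)) stop("no non-outlier trials", call. = FALSE)
  err <- rt - mean(keep_rt)
  comp <- c(rt[-1] - rt[-length(rt)], NA)
  ok <- !out & c(!out[-1], FALSE) & !is.na(comp)
  edges <- c(-2, -1, 0, 1, 2) * M
  bin_of <- function(e) {
    if (convention == "exp1") {
      # (-2M,-M], (-M,0], (0,M], (M,2M]
      if (e <= edges[1] || e > edges[5]) return(NA_integer_)
      which(e <= edges[-1] & e > edges[-5])[1]
    } else {
      # [-2M,-M), [-M,0), [0,M), [M,2M)
      if (e < edges[1] || e >= edges[5]) return(NA_integer_)
      which(e < edges[-1] & e >= edges[-5])[1]
    }
  }
  bins <- vapply(err, bin_of, integer(1))
  res <- data.frame(bin = 1:4, lower = edges[1:4], upper = edges[2:5],
                    n_pairs = 0L, mean_compensation = NA_real_)
  for (b in 1:4) {
    sel <- ok & !is.na(bins) & bins == b
    res$n_pairs[b] <- sum(sel)
    if (any(sel)) res$mean_compensation[b] <- mean(comp[sel])
  }
  structure(res, M = M, convention = convention,
            class = c("compensation_table", "data.frame"))
}

#' Split-half check for learning effects
#'
#' Compares the mean response time of the first half of a session with the
#' second half (outliers excluded from the means): per participant a pooled
#' two-sample t test between halves, and across participants a paired t
#' test on the half-means. Sessions are expected to hold 100 trials
#' (halves of 50); other lengths are split proportionally with a warning.
#'
#' @param table A multi-participant `trial_table` (single condition), with
#'   columns `participant_id`, `trial_index`, `response_time_ms`, `outlier`.
#' @return A list with `per_participant` (data frame: `participant_id`,
#'   `mean_first`, `mean_last`, `t`, `df`, `p`) and `across` (paired-t
#'   summary from [paired_stats()], or `NULL` for a single participant).
#' @export
split_half_check <- function(table) {
  stopifnot(is.data.frame(table))
  ids <- unique(table$participant_id)
  rows <- lapply(ids, function(id) {
    s <- table[table$participant_id == id, ]
    s <- s[order(s$trial_index), ]
    n <- nrow(s)
    if (n != 100)
      warning(sprintf("participant %s has %d trials; splitting at n/2", id, n),
              call. = FALSE)
    cut <- floor(n / 2)
    first <- s$response_time_ms[seq_len(cut)][!s$outlier[seq_len(cut)]]
    last <- s$response_time_ms[(cut + 1):n][!s$outlier[(cut + 1):n]]
    if (stats::sd(c(first, last)) == 0) {
      tt <- list(statistic = 0, parameter = length(first) + length(last) - 2,
                 p.value = 1)
    } else {
      tt <- stats::t.test(first, last, var.equal = TRUE)
    }
    data.frame(participant_id = id, mean_first = mean(first),
               mean_last = mean(last), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  per <- do.call(rbind, rows)
  across <- if (nrow(per) >= 2 && stats::sd(per$mean_first - per$mean_last) > 0)
    paired_stats(per$mean_first, per$mean_last) else NULL
  list(per_participant = per, across = across)
}

#' Paired t test with Cohen's d
#'
#' Paired t statistic with `n - 1` degrees of freedom and the paired-sample
#' effect size `d = mean(a - b) / sd(a - b)`.
#'
#' @param a,b Numeric vectors of equal length >= 2 (one value per
#'   participant).
#' @return A list: `t`, `df`, `p`, `cohen_d`, `mean_diff`.
#' @export
#' @examples
#' paired_stats(c(2, 4, 6, 8), c(1, 2, 3, 4))  # t ~ 3.873
paired_stats <- function(a, b) {
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("zero variance of differences: paired t undefined", call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohen_d = mean(d) / stats::sd(d), mean_diff = mean(d))
}

#' Read and write trial logs
#'
#' Trial logs are comma-separated text with a header
#' `participant_id,condition,trial_index,response_time_ms` (a
#' `foreperiod_ms` column is kept when present) and an optional
#' machine-readable metadata block of leading `#` lines (`# key: value`,
#' e.g. seed and configuration hash).
#'
#' @param path File path.
#' @param table Data frame with at least the four standard columns.
#' @param metadata Named list written as `# key: value` header lines.
#' @return `read_trial_log()` returns the data frame with any metadata in
#'   `attr(, "metadata")`; `write_trial_log()` returns `path` invisibly.
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "trial_index", "response_time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- list()
  for (m in sub("^#\\s*", "", meta_lines)) {
    kv <- regmatches(m, regexec("^([^:]+):\\s*(.*)$", m))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  attr(df, "metadata") <- meta
  df
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(table, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, format(metadata[[k]])), con)
  utils::write.csv(as.data.frame(table)[, intersect(
    c("participant_id", "condition", "trial_index", "response_time_ms",
      "foreperiod_ms", "gain", "miss", "outlier"), names(table))],
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
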