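#' Piecewise-linear gain functions
#'
#' A gain function maps an executed response time (ms) to the points earned
#' on one trial. All gain functions handled by this package are piecewise
#' linear: the real line is partitioned into `k + 1` segments by `k`
#' breakpoints, and each segment carries its own slope (points/ms) and
#' intercept (points). Boundary membership is explicit: `left_closed[i]`
#' says whether breakpoint `i` belongs to the segment on its left, so
#' discontinuous payoffs such as a reward that "plunges to zero" just past
#' the target are represented exactly, including which side of the cliff
#' the boundary time pays out on.
#'
#' @param breaks Numeric vector of strictly increasing breakpoints (ms).
#'   May be empty for a single-segment (globally linear) gain.
#' @param slopes Numeric vector of segment slopes, length `length(breaks) + 1`.
#' @param intercepts Numeric vector of segment intercepts, same length as
#'   `slopes`. Segment `j` pays `slopes[j] * t + intercepts[j]`.
#' @param left_closed Logical vector, one per breakpoint: `TRUE` if the
#'   breakpoint time itself is paid by the segment to its left.
#' @param label Character label; one of `"no_risk"`, `"step"`,
#'   `"risk_after"`, `"risk_before"` for the canonical functions, anything
#'   else is treated as `"custom"`.
#' @param target Target time in ms (the time the task rewards maximally for
#'   the canonical shapes). Used to centre optimiser brackets and resolve
#'   ties; stored, not enforced.
#'
#' @return An object of class `gain_function`.
#' @seealso [gain_no_risk()], [gain_step()], [gain_risk_after()],
#'   [gain_risk_before()], [gain_value()], [expected_gain()]
#' @export
#' @examples
#' g <- gain_function(breaks = 2300, slopes = c(1 / 23, -1 / 23),
#'                    intercepts = c(0, 200), left_closed = TRUE,
#'                    label = "no_risk")
#' gain_value(g, c(0, 2300, 2530))
gain_function <- function(breaks, slopes, intercepts, left_closed,
                          label = "custom", target = 2300) {
  breaks <- as.numeric(breaks)
  slopes <- as.numeric(slopes)
  intercepts <- as.numeric(intercepts)
  left_closed <- as.logical(left_closed)
  if (length(breaks) && any(diff(breaks) <= 0))
    stop("`breaks` must be strictly increasing", call. = FALSE)
  if (length(slopes) != length(breaks) + 1L)
    stop("need exactly length(breaks) + 1 segments", call. = FALSE)
  if (length(intercepts) != length(slopes))
    stop("`slopes` and `intercepts` must have equal length", call. = FALSE)
  if (length(left_closed) != length(breaks))
    stop("`left_closed` must have one entry per breakpoint", call. = FALSE)
  if (any(!is.finite(c(breaks, slopes, intercepts))))
    stop("gain function parameters must be finite", call. = FALSE)
  if (!is.character(label) || length(label) != 1L)
    stop("`label` must be a single string", call. = FALSE)
  structure(
    list(breaks = breaks, slopes = slopes, intercepts = intercepts,
         left_closed = left_closed, label = label, target = as.numeric(target)),
    class = "gain_function"
  )
}

canonical_labels <- c("no_risk", "step", "risk_after", "risk_before")

#' Canonical gain functions of the coincident-timing task
#'
#' The four payoff schedules of the task: a trial earns points as a function
#' of response time `t` (ms), with a target time of 2300 ms and a maximum
#' one-trial gain of 100 points.
#'
#' * `gain_no_risk()`: symmetric tent, `t/23` up to the target and
#'   `-t/23 + 200` after it; every response earns something, no miss is
#'   possible in the plausible range.
#' * `gain_step()`: 100 points anywhere in the closed window
#'   `[target - 400, target + 400]`, zero outside it.
#' * `gain_risk_after()`: `t/23` up to and including the target, zero
#'   afterwards — reward rises right up to the cliff edge.
#' * `gain_risk_before()`: mirror image, zero before the target and
#'   `-t/23 + 200` from the target on.
#'
#' Boundary membership follows the printed inequalities of the task: at
#' exactly the target time both asymmetric schedules pay 100. An optional
#' `target` translates the whole shape along the time axis for simulation
#' studies (the 2300-ms default is the experimental task).
#'
#' @param target Target time (ms); the canonical shapes are translated so
#'   their 100-point peak/window centre sits at `target`.
#' @return A [gain_function()].
#' @export
gain_no_risk <- function(target = 2300) {
  shift_gain(gain_function(
    breaks = 2300, slopes = c(1 / 23, -1 / 23), intercepts = c(0, 200),
    left_closed = TRUE, label = "no_risk", target = 2300), target - 2300)
}

#' @rdname gain_no_risk
#' @export
gain_step <- function(target = 2300) {
  shift_gain(gain_function(
    breaks = c(1900, 2700), slopes = c(0, 0, 0), intercepts = c(0, 100, 0),
    left_closed = c(FALSE, TRUE), label = "step", target = 2300),
    target - 2300)
}

#' @rdname gain_no_risk
#' @export
gain_risk_after <- function(target = 2300) {
  shift_gain(gain_function(
    breaks = 2300, slopes = c(1 / 23, 0), intercepts = c(0, 0),
    left_closed = TRUE, label = "risk_after", target = 2300), target - 2300)
}

#' @rdname gain_no_risk
#' @export
gain_risk_before <- function(target = 2300) {
  shift_gain(gain_function(
    breaks = 2300, slopes = c(0, -1 / 23), intercepts = c(0, 200),
    left_closed = FALSE, label = "risk_before", target = 2300), target - 2300)
}

# translate a gain function by dt ms without changing its values:
# G'(t) = G(t - dt), so each segment's intercept picks up slope * dt.
shift_gain <- function(g, dt) {
  if (dt == 0) return(g)
  g$breaks <- g$breaks + dt
  g$intercepts <- g$intercepts - g$slopes * dt
  g$target <- g$target + dt
  g
}

# segment index (1-based) containing each time, honouring boundary membership
segment_index <- function(g, t) {
  if (!length(g$breaks)) return(rep_len(1L, length(t)))
  idx <- rep_len(0L, length(t))
  for (i in seq_along(g$breaks)) {
    b <- g$breaks[i]
    idx <- idx + (t > b) + (t == b & g$left_closed[i] == FALSE)
  }
  idx + 1L
}

#' Evaluate a gain function
#'
#' @param g A [gain_function()].
#' @param t Numeric vector of response times (ms); must be finite.
#' @return Numeric vector of gains (points), same length as `t`.
#' @export
#' @examples
#' gain_value(gain_risk_after(), c(1150, 2300, 2300.001))
gain_value <- function(g, t) {
  stopifnot(inherits(g, "gain_function"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  j <- segment_index(g, t)
  g$slopes[j] * t + g$intercepts[j]
}

#' Supremum and argmax of a piecewise-linear gain
#'
#' `gain_max()` returns the largest attainable gain (`Inf` if an unbounded
#' outer segment rises without limit). `gain_argmax()` returns a single
#' maximising time, breaking ties by proximity to the stored target time and
#' then by the smaller time; it is the degenerate sigma = 0 limit of the
#' expected-gain optimum.
#'
#' @param g A [gain_function()].
#' @return A single numeric value.
#' @keywords internal
gain_max <- function(g) {
  k <- length(g$breaks)
  if (g$slopes[1] < 0 || g$slopes[k + 1] > 0) return(Inf)
  if (!k) return(if (g$slopes[1] == 0) g$intercepts[1] else Inf)
  max(gain_value(g, rep(g$breaks, each = 3) +
                   rep(c(-1e-9, 0, 1e-9), times = k)))
}

#' @rdname gain_max
gain_argmax <- function(g) {
  k <- length(g$breaks)
  if (!k) {
    if (g$slopes[1] != 0) stop("gain is unbounded", call. = FALSE)
    return(g$target)
  }
  if (g$slopes[1] < 0 || g$slopes[k + 1] > 0)
    stop("gain is unbounded", call. = FALSE)
  # candidates: breakpoints (evaluated just either side and at the point),
  # plus the target itself in case it sits inside a flat maximal segment
  cand <- sort(unique(c(g$breaks, g$breaks - 1e-9, g$breaks + 1e-9, g$target)))
  v <- gain_value(g, cand)
  best <- v >= max(v) - 1e-12
  cand <- cand[best]
  cand[order(abs(cand - g$target), cand)][1]
}

#' @export
print.gain_function <- function(x, ...) {
  cat(sprintf("<gain_function: %s, target %g ms, %d segment(s)>\n",
              x$label, x$target, length(x$slopes)))
  lo <- c(-Inf, x$breaks)
  hi <- c(x$breaks, Inf)
  for (j in seq_along(x$slopes)) {
    lb <- if (j == 1L) "(" else if (x$left_closed[j - 1L]) "(" else "["
    rb <- if (j == length(x$slopes)) ")" else if (x$left_closed[j]) "]" else ")"
    cat(sprintf("  %s%g, %g%s  G(t) = %g t + %g\n",
                lb, lo[j], hi[j], rb, x$slopes[j], x$intercepts[j]))
  }
  invisible(x)
}

#' Read and write gain-function configurations
#'
#' Gain functions serialise to a small YAML document listing breakpoints,
#' slopes, intercepts, boundary membership, label and target time (times in
#' ms, gains in points), so payoff schedules can travel with a run
#' configuration as plain text.
#'
#' @param g A [gain_function()].
#' @param path File path.
#' @return `read_gain_config()` returns a [gain_function()];
#'   `write_gain_config()` returns `path` invisibly.
#' @export
write_gain_config <- function(g, path) {
  stopifnot(inherits(g, "gain_function"))
  yaml::write_yaml(list(
    label = g$label, target = g$target, breaks = as.list(g$breaks),
    slopes = as.list(g$slopes), intercepts = as.list(g$intercepts),
    left_closed = as.list(g$left_closed)), path)
  invisible(path)
}

#' @rdname write_gain_config
#' @export
read_gain_config <- function(path) {
  x <- yaml::read_yaml(path)
  gain_function(breaks = unlist(x$breaks), slopes = unlist(x$slopes),
                intercepts = unlist(x$intercepts),
                left_closed = unlist(x$left_closed),
                label = x$label, target = x$target)
}

# resolve a condition label or gain_function argument to a gain_function
as_gain <- function(g, target = 2300) {
  if (inherits(g, "gain_function")) return(g)
  if (is.character(g) && length(g) == 1L && g %in% canonical_labels)
    return(switch(g,
                  no_risk = gain_no_risk(target),
                  step = gain_step(target),
                  risk_after = gain_risk_after(target),
                  risk_before = gain_risk_before(target)))
  stop("expected a gain_function or one of ",
       paste(canonical_labels, collapse = ", "), call. = FALSE)
}
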