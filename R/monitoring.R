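# Driving-style evaluation and impairment detection: maintain a reference
# distribution of judgment scores learned during an alert baseline, then
# slide a window over the incoming judgment stream and alarm on (a) a
# downward distribution shift (one-sided two-sample Kolmogorov-Smirnov) or
# (b) a sustained negative trend (OLS slope confirmed by a Mann-Kendall
# test).
#
# Judgments arrive at the trace sampling rate (10 Hz by default) and are
# strongly serially dependent at that timescale; both tests therefore thin
# the scores to one sample per `thin_s` seconds before testing, so that the
# nominal test level is approximately honest.

#' Build the per-driver reference distribution
#'
#' Collects the judgment scores of the first `baseline_duration` seconds of
#' a record stream into a normalised histogram over \[0, 100\].  The raw
#' baseline scores are kept alongside the histogram: the window comparison
#' test works on the empirical distribution itself.
#'
#' @param records Data frame with columns `t` and `score` (output of
#'   [judge_trace()]).
#' @param baseline_duration Length of the baseline interval, seconds.
#' @param bins Number of histogram bins over \[0, 100\] (default 20).
#' @param min_samples Minimum number of baseline records before the
#'   reference is usable.
#' @return A list of class `reference_distribution` with fields
#'   `bin_edges`, `probabilities`, `n_samples`, `source_interval`,
#'   `scores`, `times`, `mean_score`.
#' @export
build_reference <- function(records, baseline_duration = 600, bins = 20L,
                            min_samples = 100L) {
  if (!all(c("t", "score") %in% names(records)))
    lw_stop("records must have columns t and score", "lw_invalid_input")
  if (nrow(records) == 0)
    lw_stop("empty record stream: reference not ready", "lw_not_ready")
  t0 <- records$t[1]
  if (max(records$t) - t0 < baseline_duration)
    lw_stop(sprintf("records span %.1f s < baseline of %.1f s: reference not ready",
                    max(records$t) - t0, baseline_duration), "lw_not_ready")
  base <- records[records$t < t0 + baseline_duration, , drop = FALSE]
  if (nrow(base) < min_samples)
    lw_stop(sprintf("only %d baseline records < required %d: reference not ready",
                    nrow(base), min_samples), "lw_not_ready")
  if (any(base$score < 0 | base$score > 100))
    lw_stop("scores must lie in [0, 100]", "lw_invalid_input")
  edges <- seq(0, 100, length.out = bins + 1)
  idx <- findInterval(base$score, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  structure(
    list(bin_edges = edges, probabilities = counts / nrow(base),
         n_samples = nrow(base),
         source_interval = c(t_start = t0, t_end = t0 + baseline_duration),
         scores = base$score, times = base$t,
         mean_score = mean(base$score)),
    class = "reference_distribution"
  )
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("<reference_distribution> n = %d over [%.1f, %.1f] s, mean score %.2f\n",
              x$n_samples, x$source_interval[1], x$source_interval[2], x$mean_score))
  invisible(x)
}

# Thin a set of (t, score) points to one sample per `thin_s` seconds,
# keeping the first sample of each bin.  thin_s = 0 keeps everything.
thin_scores <- function(t, score, thin_s) {
  if (thin_s <= 0 || length(t) < 2) return(list(t = t, score = score))
  keep <- !duplicated(floor((t - t[1]) / thin_s))
  list(t = t[keep], score = score[keep])
}

#' Compare a recent window against the reference distribution
#'
#' Two-sample Kolmogorov-Smirnov statistic D between the reference scores
#' and the window scores, against the asymptotic critical value
#' `sqrt(-log(alpha/2)/2) * sqrt((n + m) / (n * m))`.  The comparison is
#' one-sided in substance: a shift only counts as impairment if the window
#' mean is below the reference mean -- an improving driver never raises an
#' alarm.
#'
#' @param ref A `reference_distribution`.
#' @param window Data frame with columns `t`, `score` (the recent records).
#' @param alpha Test level.
#' @param thin_s Thinning interval in seconds applied to both samples
#'   before testing (see [default_config()]).
#' @return List with `statistic` (D), `critical`, `is_shifted`, `n_ref`,
#'   `n_window`.
#' @export
window_compare <- function(ref, window, alpha = 0.05, thin_s = 2) {
  if (!inherits(ref, "reference_distribution"))
    lw_stop("ref must be a reference_distribution", "lw_invalid_input")
  if (is.null(window) || nrow(window) == 0)
    lw_stop("window is empty", "lw_invalid_input")
  r <- thin_scores(ref$times, ref$scores, thin_s)
  w <- thin_scores(window$t, window$score, thin_s)
  n <- length(r$score); m <- length(w$score)
  D <- unname(suppressWarnings(
    stats::ks.test(r$score, w$score)$statistic))
  crit <- sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
  list(statistic = D, critical = crit,
       is_shifted = (D > crit) && (mean(w$score) < mean(r$score)),
       n_ref = n, n_window = m)
}

#' Test a window for a declining score trend
#'
#' Ordinary least-squares slope of score against time (reported in score
#' units per minute) plus a one-sided Mann-Kendall monotonic-trend test
#' (Kendall rank correlation of score with time).  The window is declining
#' only when the slope is below `slope_threshold` *and* the Mann-Kendall
#' test rejects at `alpha`: the slope gives magnitude, the rank test a
#' distribution-free confirmation of monotonicity.
#'
#' @param window Data frame with columns `t`, `score`.
#' @param min_points Minimum number of (thinned) points required.
#' @param slope_threshold Declining-slope threshold, score units per minute
#'   (negative; default -1).
#' @param alpha Mann-Kendall test level.
#' @param thin_s Thinning interval, seconds.
#' @return List with `slope` (score/min), `p_value`, `is_declining`,
#'   `n_points`.
#' @export
trend_test <- function(window, min_points = 30L, slope_threshold = -1,
                       alpha = 0.05, thin_s = 2) {
  if (is.null(window) || nrow(window) == 0)
    lw_stop("window is empty", "lw_invalid_input")
  w <- thin_scores(window$t, window$score, thin_s)
  n <- length(w$score)
  if (n < min_points)
    lw_stop(sprintf("window has %d points < required %d", n, min_points),
            "lw_invalid_input")
  tm <- w$t / 60
  vt <- stats::var(tm)
  slope <- if (vt > 0) stats::cov(tm, w$score) / vt else 0
  p <- if (stats::var(w$score) == 0 || vt == 0) 1 else
    suppressWarnings(stats::cor.test(w$t, w$score, method = "kendall",
                                     alternative = "less")$p.value)
  list(slope = slope, p_value = p,
       is_declining = (slope < slope_threshold) && (p < alpha),
       n_points = n)
}

#' Detect driver impairment over a judgment stream
#'
#' After the baseline period, slides a comparison window of
#' `monitoring$window_s` seconds (default 10 minutes) along the stream with
#' stride `monitoring$stride_s`, applying [window_compare()] and
#' [trend_test()] at each position, and emits at most one alarm per
#' refractory period per alarm kind.
#'
#' The configured level `monitoring$alpha` is a per-trace alarm budget:
#' overlapping window positions are not independent tests, so each
#' individual test runs at the Sidak-adjusted level
#' `1 - (1 - alpha)^(1/K)` where `K` is the number of non-overlapping
#' windows that fit in the monitored span -- the effective number of
#' independent looks at the data.
#'
#' The detector is deterministic: the same records and configuration always
#' produce the same alarms.
#'
#' @param records Data frame with columns `t`, `score` ([judge_trace()]
#'   output).  A stream shorter than the baseline yields no alarms (with a
#'   warning).
#' @param config Pipeline configuration; thresholds under
#'   `config$monitoring`.
#' @return Data frame of class `alarm_log` with columns `t`, `kind`
#'   (`distribution_shift` or `negative_trend`), `statistic`, `threshold`,
#'   `window_start`, `window_end`.
#' @export
detect_impairment <- function(records, config = default_config()) {
  mc <- config$monitoring
  empty <- data.frame(t = numeric(), kind = character(),
                      statistic = numeric(), threshold = numeric(),
                      window_start = numeric(), window_end = numeric())
  class(empty) <- c("alarm_log", "data.frame")
  if (nrow(records) == 0) {
    warning("empty record stream; no alarms evaluated")
    return(empty)
  }
  t0 <- records$t[1]
  t_end <- records$t[nrow(records)]
  ref <- tryCatch(
    build_reference(records, mc$baseline_s, mc$bins, mc$min_ref_samples),
    lw_not_ready = function(e) {
      warning(sprintf("no alarms evaluated: %s", conditionMessage(e)))
      NULL
    })
  if (is.null(ref)) return(empty)
  first_eval <- t0 + mc$baseline_s + mc$window_s
  if (t_end < first_eval) {
    warning("stream ends before the first full comparison window; no alarms evaluated")
    return(empty)
  }
  eval_times <- seq(first_eval, t_end, by = mc$stride_s)
  k_eff <- max(1, floor((t_end - (t0 + mc$baseline_s)) / mc$window_s))
  alpha_w <- 1 - (1 - mc$alpha)^(1 / k_eff)
  last_alarm <- c(distribution_shift = -Inf, negative_trend = -Inf)
  alarms <- list()
  for (te in eval_times) {
    win <- records[records$t > te - mc$window_s & records$t <= te, , drop = FALSE]
    if (nrow(win) == 0) next
    if (te - last_alarm[["distribution_shift"]] >= mc$refractory_s) {
      wc <- window_compare(ref, win, alpha = alpha_w, thin_s = mc$thin_s)
      if (wc$is_shifted) {
        last_alarm[["distribution_shift"]] <- te
        alarms[[length(alarms) + 1L]] <- data.frame(
          t = te, kind = "distribution_shift", statistic = wc$statistic,
          threshold = wc$critical, window_start = te - mc$window_s,
          window_end = te)
      }
    }
    if (te - last_alarm[["negative_trend"]] >= mc$refractory_s) {
      tt <- tryCatch(
        trend_test(win, min_points = mc$trend_min_points,
                   slope_threshold = mc$slope_threshold,
                   alpha = alpha_w, thin_s = mc$thin_s),
        lw_invalid_input = function(e) NULL)
      if (!is.null(tt) && tt$is_declining) {
        last_alarm[["negative_trend"]] <- te
        alarms[[length(alarms) + 1L]] <- data.frame(
          t = te, kind = "negative_trend", statistic = tt$slope,
          threshold = mc$slope_threshold, window_start = te - mc$window_s,
          window_end = te)
      }
    }
  }
  out <- if (length(alarms)) do.call(rbind, alarms) else empty
  class(out) <- c("alarm_log", "data.frame")
  rownames(out) <- NULL
  out
}
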