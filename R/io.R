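# CSV I/O for traces, judgment logs and alarm logs.  All files are
# comma-separated, '.' decimal, UTF-8, with '#'-prefixed header comment
# lines carrying provenance (package version, config fingerprint, seed).
# Numeric columns are written with 17 significant digits so a write/read
# round trip reproduces every value exactly.

lw_write_csv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

provenance_comments <- function(what, config = NULL, seed = NULL) {
  c(sprintf("lanewatch %s %s", what,
            as.character(utils::packageVersion("lanewatch"))),
    if (!is.null(config)) sprintf("config_md5: %s", config_hash(config)),
    if (!is.null(seed)) sprintf("seed: %s", format(seed)))
}

#' Read a lane-keeping trace from CSV
#'
#' Expects columns `t` (s) and `lp_m` (m); `lp_prime_cmps` (cm/s) is used
#' when present and otherwise reconstructed by finite differences of
#' `lp_m` -- the pipeline must keep operating when one input signal is
#' missing.  `#`-prefixed lines are comments.  Timestamps must be
#' non-decreasing: a shuffled file is rejected rather than silently
#' reordered.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `t`, `lp_m`, `lp_prime_cmps` (plus any
#'   extra columns present in the file).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) lw_stop(sprintf("trace file not found: %s", path),
                                  "lw_format_error")
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("t", "lp_m"))
    if (!col %in% names(df))
      lw_stop(sprintf("trace is missing required column '%s'", col),
              "lw_format_error")
  if (nrow(df) == 0) lw_stop("trace has no rows", "lw_format_error")
  if (!all(is.finite(df$t)) || !all(is.finite(df$lp_m)))
    lw_stop("t and lp_m must be finite", "lw_format_error")
  bad <- which(diff(df$t) < 0)
  if (length(bad))
    lw_stop(sprintf("timestamps are not non-decreasing at row %d", bad[1] + 1L),
            "lw_format_error")
  if (!"lp_prime_cmps" %in% names(df)) {
    n <- nrow(df)
    if (n == 1L) {
      df$lp_prime_cmps <- 0
    } else {
      dtv <- diff(df$t)
      dlp <- ifelse(dtv > 0, diff(df$lp_m) / dtv, 0) * 100
      df$lp_prime_cmps <- c(dlp, dlp[n - 1L])
    }
  }
  df
}

#' Write a lane-keeping trace to CSV
#'
#' @param samples Trace data frame (see [simulate_trace()]).
#' @param path Output path.
#' @param config,seed Optional provenance recorded in `#` header comments.
#' @return The path, invisibly.
#' @export
write_trace <- function(samples, path, config = NULL, seed = NULL) {
  lw_write_csv(samples, path, provenance_comments("trace", config, seed))
}

#' Write / read a judgment log
#'
#' Columns `t`, `score` and, when present, `fired_rules`
#' (semicolon-joined).
#'
#' @param judgments Data frame from [judge_trace()].
#' @param path File path.
#' @param config,seed Optional provenance header fields.
#' @return `write_judgments()` the path invisibly; `read_judgments()` the
#'   data frame.
#' @export
write_judgments <- function(judgments, path, config = NULL, seed = NULL) {
  lw_write_csv(judgments, path, provenance_comments("judgments", config, seed))
}

#' @rdname write_judgments
#' @export
read_judgments <- function(path) {
  if (!file.exists(path)) lw_stop(sprintf("file not found: %s", path),
                                  "lw_format_error")
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t", "score") %in% names(df)))
    lw_stop("judgment log must have columns t and score", "lw_format_error")
  df
}

#' Write an alarm log
#'
#' Columns `t`, `kind`, `statistic`, `threshold`, `window_start`,
#' `window_end`.
#'
#' @param alarms Data frame from [detect_impairment()].
#' @param path File path.
#' @param config,seed Optional provenance header fields.
#' @return The path, invisibly.
#' @export
write_alarms <- function(alarms, path, config = NULL, seed = NULL) {
  lw_write_csv(alarms, path, provenance_comments("alarms", config, seed))
}
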