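# Pipeline configuration: partitions, rule matrix, defuzzification
# resolution, monitoring thresholds.  Loadable from YAML or JSON; every
# omitted field falls back to the documented default.

#' Default pipeline configuration
#'
#' Returns the complete configuration of the detector:
#' * `partitions$lp`: 5 triangular Ruspini sets `Sx+, Sx, C, Dx, Dx+` on
#'   the lateral-position universe \[-2, 2\] m (positive to the right);
#' * `partitions$lp_prime`: the same 5 labels on the drift universe
#'   \[-20, 20\] cm/s;
#' * `partitions$judgment`: 5 sets `Us+, Us, NSS, S, S+` on the judgment
#'   scale \[0, 100\];
#' * `rules`: the [default_rule_matrix()];
#' * `defuzz_resolution`: 1001 grid points for centre-of-areas;
#' * `lp_prime_sign`: +1; set to -1 when the trace source logs drift
#'   positive towards the left lane edge instead of the right;
#' * `monitoring`: alarm thresholds, see [detect_impairment()] --
#'   `alpha` (0.05), `bins` (20), `baseline_s` (600), `window_s` (600),
#'   `stride_s` (60), `thin_s` (2), `slope_threshold` (-1 score/min),
#'   `trend_min_points` (30), `refractory_s` (300), `min_ref_samples` (100).
#'
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function() {
  in_labels <- c("Sx+", "Sx", "C", "Dx", "Dx+")
  out_labels <- c("Us+", "Us", "NSS", "S", "S+")
  cfg <- list(
    partitions = list(
      lp = make_ruspini_partition(-2, 2, in_labels),
      lp_prime = make_ruspini_partition(-20, 20, in_labels),
      judgment = make_ruspini_partition(0, 100, out_labels)
    ),
    rules = default_rule_matrix(),
    defuzz_resolution = 1001L,
    lp_prime_sign = 1,
    monitoring = list(
      alpha = 0.05,
      bins = 20L,
      baseline_s = 600,
      window_s = 600,
      stride_s = 60,
      thin_s = 2,
      slope_threshold = -1,
      trend_min_points = 30L,
      refractory_s = 300,
      min_ref_samples = 100L
    )
  )
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks label consistency between the partitions and the rule matrix and
#' legality of every monitoring threshold.
#'
#' @param cfg A configuration list.
#' @return The validated configuration, classed `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  p <- cfg$partitions
  for (nm in c("lp", "lp_prime", "judgment"))
    if (!inherits(p[[nm]], "fuzzy_partition"))
      lw_stop(sprintf("partition '%s' is missing or invalid", nm), "lw_invalid_config")
  m <- cfg$rules
  if (!inherits(m, "rule_matrix")) lw_stop("rules must be a rule_matrix", "lw_invalid_config")
  if (!identical(m$lp_labels, p$lp$labels) ||
      !identical(m$lpp_labels, p$lp_prime$labels))
    lw_stop("rule matrix labels do not match the input partitions", "lw_invalid_config")
  if (!all(m$grid %in% p$judgment$labels))
    lw_stop("rule matrix outputs are not all judgment labels", "lw_invalid_config")
  if (cfg$defuzz_resolution < 101)
    lw_stop("defuzz_resolution must be at least 101", "lw_invalid_config")
  if (!cfg$lp_prime_sign %in% c(-1, 1))
    lw_stop("lp_prime_sign must be +1 or -1", "lw_invalid_config")
  mc <- cfg$monitoring
  chk <- function(ok, what) if (!ok) lw_stop(paste("monitoring:", what), "lw_invalid_config")
  chk(is.numeric(mc$alpha) && mc$alpha > 0 && mc$alpha < 1, "alpha must be in (0,1)")
  chk(mc$bins >= 2, "bins must be >= 2")
  chk(mc$baseline_s > 0, "baseline_s must be positive")
  chk(mc$window_s > 0, "window_s must be positive")
  chk(mc$stride_s > 0, "stride_s must be positive")
  chk(mc$thin_s >= 0, "thin_s must be non-negative")
  chk(is.numeric(mc$slope_threshold) && mc$slope_threshold < 0,
      "slope_threshold must be negative (score units per minute)")
  chk(mc$trend_min_points >= 3, "trend_min_points must be >= 3")
  chk(mc$refractory_s >= 0, "refractory_s must be non-negative")
  chk(mc$min_ref_samples >= 2, "min_ref_samples must be >= 2")
  structure(cfg, class = "pipeline_config")
}

# Build one partition from its configuration block.  Explicit per-label
# breakpoints (3 = triangular, 4 = trapezoidal) override the default
# Ruspini construction.
partition_from_list <- function(spec) {
  lo <- spec$lo; hi <- spec$hi
  labels <- as.character(spec$labels)
  if (is.null(spec$breakpoints))
    return(make_ruspini_partition(lo, hi, labels))
  fns <- lapply(labels, function(lab) {
    bp <- spec$breakpoints[[lab]]
    if (is.null(bp)) lw_stop(sprintf("missing breakpoints for label '%s'", lab),
                             "lw_invalid_config")
    switch(as.character(length(bp)),
           "3" = mf_triangular(bp[1], bp[2], bp[3]),
           "4" = mf_trapezoidal(bp[1], bp[2], bp[3], bp[4]),
           lw_stop("breakpoints must list 3 (triangular) or 4 (trapezoidal) values",
                   "lw_invalid_config"))
  })
  fuzzy_partition(lo, hi, labels, fns)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Any field omitted from the file keeps its [default_config()] value.
#' Partitions may carry explicit `breakpoints` per label; without them the
#' Ruspini construction is used.  The rule matrix is given as a list of
#' rows keyed by the LP labels, each row an ordered list of output labels
#' (one per LP' label).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) lw_stop(sprintf("config file not found: %s", path),
                                  "lw_invalid_config")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- unclass(default_config())

  if (!is.null(raw$partitions)) {
    for (nm in names(raw$partitions)) {
      if (!nm %in% c("lp", "lp_prime", "judgment"))
        lw_stop(sprintf("unknown partition '%s'", nm), "lw_invalid_config")
      cfg$partitions[[nm]] <- partition_from_list(raw$partitions[[nm]])
    }
  }
  if (!is.null(raw$rules)) {
    lp_labs <- cfg$partitions$lp$labels
    lpp_labs <- cfg$partitions$lp_prime$labels
    rows <- raw$rules
    if (!setequal(names(rows), lp_labs))
      lw_stop("rule rows must be keyed by the LP labels", "lw_invalid_config")
    grid <- do.call(rbind, lapply(lp_labs, function(r) unlist(rows[[r]])))
    cfg$rules <- rule_matrix(grid, lp_labs, lpp_labs,
                             output_labels = cfg$partitions$judgment$labels)
  }
  if (!is.null(raw$defuzz_resolution))
    cfg$defuzz_resolution <- as.integer(raw$defuzz_resolution)
  if (!is.null(raw$lp_prime_sign)) cfg$lp_prime_sign <- raw$lp_prime_sign
  if (!is.null(raw$monitoring))
    cfg$monitoring <- utils::modifyList(cfg$monitoring, raw$monitoring)
  if (!is.null(raw$scenario)) cfg$scenario <- scenario_from_list(raw$scenario)
  validate_config(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  LP:       "); print(x$partitions$lp)
  cat("  LP':      "); print(x$partitions$lp_prime)
  cat("  judgment: "); print(x$partitions$judgment)
  cat(sprintf("  defuzz resolution: %d; LP' sign: %+d\n",
              x$defuzz_resolution, x$lp_prime_sign))
  mc <- x$monitoring
  cat(sprintf("  monitoring: alpha=%g baseline=%gs window=%gs stride=%gs thin=%gs\n",
              mc$alpha, mc$baseline_s, mc$window_s, mc$stride_s, mc$thin_s))
  invisible(x)
}

# Stable fingerprint of a configuration, for output-file provenance
# headers.  Hashes the deparsed structure through tools::md5sum.
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "scenario")]), f)
  unname(tools::md5sum(f))
}
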