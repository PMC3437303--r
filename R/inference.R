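# Mamdani inference: 5x5 safety rule matrix, min/max activation, centre of
# areas defuzzification onto the 0-100 judgment scale.

#' Construct a rule matrix
#'
#' @param grid Character matrix of output labels; rows indexed by the
#'   lateral-position labels, columns by the drift labels.
#' @param lp_labels,lpp_labels Ordered input labels naming the rows/columns.
#' @param output_labels Legal output labels (the judgment partition labels).
#' @return An object of class `rule_matrix`.
#' @export
rule_matrix <- function(grid, lp_labels, lpp_labels,
                        output_labels = c("Us+", "Us", "NSS", "S", "S+")) {
  grid <- as.matrix(grid)
  if (nrow(grid) != length(lp_labels) || ncol(grid) != length(lpp_labels))
    lw_stop("rule grid dimensions must match the input label counts", "lw_invalid_config")
  if (any(is.na(grid)) || !all(grid %in% output_labels))
    lw_stop(sprintf("every rule cell must hold one of: %s",
                    paste(output_labels, collapse = ", ")), "lw_invalid_config")
  dimnames(grid) <- list(lp_labels, lpp_labels)
  structure(list(lp_labels = lp_labels, lpp_labels = lpp_labels,
                 output_labels = output_labels, grid = grid),
            class = "rule_matrix")
}

#' @export
print.rule_matrix <- function(x, ...) {
  cat("<rule_matrix> rows = LP, cols = LP'\n")
  print(x$grid)
  invisible(x)
}

#' Default safety rule matrix
#'
#' Encodes the governing principle of the judgment: input combinations that
#' make the vehicle converge towards the lane centre are safe, combinations
#' that make it diverge are unsafe.  With both variables positive towards
#' the right lane edge, an offset to one side with a drift of the opposite
#' sign is corrective (high judgment), while an offset with a same-sign
#' drift is divergent and can lead off track (low judgment).  Convergence
#' is graded purely: at a moderate offset any leftward drift counts as
#' corrective, so along the `Dx` row the judgment is monotone non-increasing
#' as the drift turns from strongly corrective to strongly divergent.  The
#' matrix is point-symmetric: mirroring both inputs leaves the judgment
#' unchanged.
#'
#' @return A `rule_matrix` over LP rows `Sx+, Sx, C, Dx, Dx+` and LP'
#'   columns in the same order, with outputs in `Us+, Us, NSS, S, S+`.
#' @export
#' @examples
#' m <- default_rule_matrix()
#' m$grid["C", "C"]     # centred, no drift: very safe
#' m$grid["Dx+", "Dx+"] # far right, drifting strongly right: very unsafe
default_rule_matrix <- function() {
  labs <- c("Sx+", "Sx", "C", "Dx", "Dx+")
  row_c   <- c("NSS", "S", "S+", "S", "NSS")
  row_dx  <- c("S+", "S+", "NSS", "Us", "Us+")
  row_dxp <- c("S", "NSS", "Us", "Us+", "Us+")
  grid <- rbind(
    `Sx+` = rev(row_dxp),
    `Sx`  = rev(row_dx),
    `C`   = row_c,
    `Dx`  = row_dx,
    `Dx+` = row_dxp
  )
  rule_matrix(grid, labs, labs)
}

#' Apply the rule matrix to fuzzified inputs
#'
#' Classic Mamdani activation: each rule "If LP is X and LP' is Y then J is
#' Z" fires with strength `min(degree(X), degree(Y))`; per output label the
#' strengths of all rules concluding that label are aggregated by `max`.
#' Under the default Ruspini partitions a crisp input pair activates at most
#' two sets per input, so at most four rules fire.
#'
#' @param act_lp,act_lpp Named activation vectors as returned by
#'   [fuzzify()] for a single crisp value.
#' @param m A `rule_matrix`.
#' @return Named numeric vector of output-label activations.
#' @export
infer <- function(act_lp, act_lpp, m) {
  if (!inherits(m, "rule_matrix")) lw_stop("m must be a rule_matrix", "lw_invalid_config")
  if (!identical(names(act_lp), m$lp_labels) || !identical(names(act_lpp), m$lpp_labels))
    lw_stop("activation labels do not match the rule matrix labels", "lw_invalid_config")
  drop(infer_bulk(rbind(act_lp), rbind(act_lpp), m))
}

# Vectorised rule activation: A, B are n x label matrices of input
# activations; returns an n x output-label activation matrix.
infer_bulk <- function(A, B, m) {
  out <- matrix(0, nrow(A), length(m$output_labels),
                dimnames = list(NULL, m$output_labels))
  for (i in seq_along(m$lp_labels)) {
    for (j in seq_along(m$lpp_labels)) {
      lab <- m$grid[i, j]
      out[, lab] <- pmax(out[, lab], pmin(A[, i], B[, j]))
    }
  }
  out
}

#' Defuzzify output activations by centre of areas
#'
#' Clips each output membership function at its activation strength, takes
#' the pointwise maximum envelope on an evenly spaced grid over the output
#' universe, and returns the centroid `sum(x * mu(x)) / sum(mu(x))`, both
#' sums trapezoid-weighted so the envelope integrals converge at second
#' order in the grid spacing (the shouldered end sets carry mass at the
#' universe edges).
#'
#' @param output_partition The judgment `fuzzy_partition` (0-100 scale).
#' @param act Named activation vector over the output labels.
#' @param resolution Number of grid points, at least 101.  Default 1001.
#' @return The crisp score, a value inside the output universe.
#' @export
#' @examples
#' out <- make_ruspini_partition(0, 100, c("Us+", "Us", "NSS", "S", "S+"))
#' defuzzify_coa(out, c("Us+" = 0, "Us" = 0, "NSS" = 1, "S" = 0, "S+" = 0))
defuzzify_coa <- function(output_partition, act, resolution = 1001L) {
  if (!inherits(output_partition, "fuzzy_partition"))
    lw_stop("output_partition must be a fuzzy_partition", "lw_invalid_config")
  if (resolution < 101) lw_stop("resolution must be at least 101", "lw_invalid_config")
  if (!identical(names(act), output_partition$labels))
    lw_stop("activation labels do not match the output partition", "lw_invalid_config")
  if (all(act <= 0))
    lw_stop("no rule fired: all output activations are zero", "lw_no_rule_fired")
  drop(defuzzify_bulk(output_partition, rbind(act), resolution))
}

# Vectorised COA over an n x label activation matrix; the per-sample
# envelope/centroid loop is compiled (src/coa.cpp).
defuzzify_bulk <- function(output_partition, act, resolution = 1001L) {
  xs <- seq(output_partition$universe_lo, output_partition$universe_hi,
            length.out = resolution)
  M <- vapply(output_partition$functions, membership, numeric(resolution), x = xs)
  coa_scores_cpp(act, M, xs)
}

#' Judge a single lateral sample
#'
#' Composes the full pipeline for one time point: fuzzify the lateral
#' position and the drift, activate the rule matrix, defuzzify by centre of
#' areas.  Records the fired rules alongside the crisp 0-100 score.
#'
#' @param sample A list or one-row data frame with fields `t` (s), `lp_m`
#'   (m) and `lp_prime_cmps` (cm/s).
#' @param config A pipeline configuration, see [default_config()].
#' @return A list of class `judgment_record` with elements `t`, `score`,
#'   `output_activations` and `fired_rules` (a data frame with columns
#'   `lp_label`, `lpp_label`, `output_label`, `strength`).
#' @export
#' @examples
#' judge(list(t = 0, lp_m = 0, lp_prime_cmps = 0))$score
judge <- function(sample, config = default_config()) {
  act_lp <- fuzzify(config$partitions$lp, sample$lp_m)
  act_lpp <- fuzzify(config$partitions$lp_prime,
                     config$lp_prime_sign * sample$lp_prime_cmps)
  act_out <- infer(act_lp, act_lpp, config$rules)
  score <- defuzzify_coa(config$partitions$judgment, act_out,
                         config$defuzz_resolution)
  m <- config$rules
  fired <- which(outer(act_lp, act_lpp, pmin) > 0, arr.ind = TRUE)
  rules <- data.frame(
    lp_label = m$lp_labels[fired[, 1]],
    lpp_label = m$lpp_labels[fired[, 2]],
    output_label = m$grid[fired],
    strength = pmin(act_lp[fired[, 1]], act_lpp[fired[, 2]]),
    row.names = NULL
  )
  structure(list(t = sample$t, score = score,
                 output_activations = act_out, fired_rules = rules),
            class = "judgment_record")
}

#' @export
print.judgment_record <- function(x, ...) {
  cat(sprintf("<judgment_record> t = %g s, score = %.2f (%d rules fired)\n",
              x$t, x$score, nrow(x$fired_rules)))
  invisible(x)
}

#' Judge every sample of a trace
#'
#' Vectorised pipeline over a whole trace.  If an input pair activates no
#' rule (impossible for finite inputs under the default clamping
#' fuzzification, but reachable with user-supplied partitions that do not
#' cover the universe), the previous score is carried forward -- or the
#' neutral 50 if there is none -- and a warning is raised.
#'
#' @param trace Data frame with columns `t`, `lp_m`, `lp_prime_cmps`.
#' @param config Pipeline configuration, see [default_config()].
#' @param include_rules If `TRUE`, adds a `fired_rules` character column
#'   ("LP&LP'>OUT:strength" terms joined by ";").  Off by default: it is the
#'   expensive part of the record and bulk scoring rarely needs it.
#' @return Data frame with columns `t`, `score` (and optionally
#'   `fired_rules`).
#' @export
judge_trace <- function(trace, config = default_config(), include_rules = FALSE) {
  req <- c("t", "lp_m", "lp_prime_cmps")
  if (!all(req %in% names(trace)))
    lw_stop("trace must have columns t, lp_m, lp_prime_cmps", "lw_invalid_input")
  if (nrow(trace) == 0) return(data.frame(t = numeric(), score = numeric()))
  A <- fuzzify(config$partitions$lp, trace$lp_m)
  B <- fuzzify(config$partitions$lp_prime,
               config$lp_prime_sign * trace$lp_prime_cmps)
  if (nrow(trace) == 1L) { A <- rbind(A); B <- rbind(B) }
  act <- infer_bulk(A, B, config$rules)
  scores <- defuzzify_bulk(config$partitions$judgment, act,
                           config$defuzz_resolution)
  if (anyNA(scores)) {
    warning("no rule fired for some samples; carrying the previous score forward")
    for (i in which(is.na(scores)))
      scores[i] <- if (i > 1L) scores[i - 1L] else 50
  }
  out <- data.frame(t = trace$t, score = scores)
  if (include_rules) {
    m <- config$rules
    out$fired_rules <- vapply(seq_len(nrow(out)), function(i) {
      s <- outer(A[i, ], B[i, ], pmin)
      f <- which(s > 0, arr.ind = TRUE)
      paste(sprintf("%s&%s>%s:%.4g", m$lp_labels[f[, 1]], m$lpp_labels[f[, 2]],
                    m$grid[f], s[f]), collapse = ";")
    }, character(1))
  }
  out
}
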