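# Shared fixtures and independent oracles.

lw_cfg <- default_config()
in_labels <- c("Sx+", "Sx", "C", "Dx", "Dx+")
out_labels <- c("Us+", "Us", "NSS", "S", "S+")

# Independent centre-of-areas oracle: builds the evenly spaced triangular
# membership family itself (shared code with the package: none) and
# integrates the clipped-max envelope by the trapezoidal rule on a fine
# grid.
oracle_coa <- function(act, lo = 0, hi = 100, n = 10001L) {
  xs <- seq(lo, hi, length.out = n)
  peaks <- seq(lo, hi, length.out = length(act))
  mu <- rep(0, n)
  for (i in seq_along(act)) {
    a <- if (i == 1) peaks[1] else peaks[i - 1]
    b <- peaks[i]
    cc <- if (i == length(act)) peaks[length(act)] else peaks[i + 1]
    up <- if (b > a) (xs - a) / (b - a) else as.numeric(xs >= b)
    dn <- if (cc > b) (cc - xs) / (cc - b) else as.numeric(xs <= b)
    mu <- pmax(mu, pmin(act[i], pmax(0, pmin(up, dn, 1))))
  }
  w <- rep(1, n)
  w[c(1, n)] <- 0.5
  sum(w * xs * mu) / sum(w * mu)
}

# Exhaustive judgment surface over lp in [-2,2] step 0.01 and lp' in
# [-20,20] step 0.1, built from integer ratios so the grid is exactly
# symmetric about 0.  Evaluated once per test run and cached.
judgment_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lp <- (-200:200) / 100
      lpp <- (-200:200) / 10
      g <- expand.grid(lp_m = lp, lp_prime_cmps = lpp,
                       KEEP.OUT.ATTRS = FALSE)
      g$t <- seq_len(nrow(g))
      s <- judge_trace(g, lw_cfg)$score
      cache <<- list(lp = lp, lpp = lpp,
                     score = matrix(s, nrow = length(lp)))
    }
    cache
  }
})

# Synthetic judgment stream: scores drawn i.i.d. at a fixed sampling rate.
score_stream <- function(scores, dt = 1) {
  data.frame(t = (seq_along(scores) - 1) * dt, score = scores)
}
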