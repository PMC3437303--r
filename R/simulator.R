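# Lane-keeping simulator: a feedback-controlled driver whose corrective
# gain decays with drowsiness and who suffers microsleep lapses.  Between
# lapses the lateral position follows a discretised Ornstein-Uhlenbeck
# process lp <- lp + dt*(-k*lp) + sigma*sqrt(dt)*eps; during a lapse the
# corrective gain is zero and the vehicle drifts at a constant bias
# velocity.  Gain, noise and lapse rate interpolate linearly from the alert
# to the drowsy profile across the decay ramp.

#' Driver control profile
#'
#' @param gain_k Corrective feedback strength, 1/s.  The alert driver
#'   recentres the vehicle with time constant `1/gain_k`.
#' @param noise_sigma Diffusion of lateral perturbations, m/sqrt(s)
#'   (road/steering noise).  Stationary lane-keeping spread without lapses
#'   is `sqrt(noise_sigma^2 / (2 * gain_k))` metres.
#' @param lapse_rate Microsleep onset rate, events/minute.
#' @param lapse_duration_mean Mean lapse duration, seconds (exponential).
#' @param lapse_bias Lateral drift velocity during a lapse, m/s (heading
#'   error with no correction).
#' @return A list of class `driver_profile`.
#' @export
driver_profile <- function(gain_k = 0.3, noise_sigma = 0.05, lapse_rate = 0,
                           lapse_duration_mean = 4, lapse_bias = 0.2) {
  if (gain_k < 0 || noise_sigma < 0 || lapse_rate < 0 || lapse_duration_mean <= 0)
    lw_stop("profile requires gain_k, noise_sigma, lapse_rate >= 0 and lapse_duration_mean > 0",
            "lw_invalid_config")
  structure(list(gain_k = gain_k, noise_sigma = noise_sigma,
                 lapse_rate = lapse_rate,
                 lapse_duration_mean = lapse_duration_mean,
                 lapse_bias = lapse_bias),
            class = "driver_profile")
}

#' Stock profiles: the attentive and the drowsy driver
#'
#' `alert_profile()` is a well-rested driver: tight feedback (k = 0.3/s),
#' small perturbations (sigma = 0.05 m/sqrt(s)), no lapses.
#' `drowsy_profile()` has degraded feedback (k = 0.05/s), larger
#' perturbations (sigma = 0.10), and microsleeps at 2/min lasting 4 s on
#' average with a 0.2 m/s drift.
#'
#' @return A `driver_profile`.
#' @export
alert_profile <- function() driver_profile()

#' @rdname alert_profile
#' @export
drowsy_profile <- function() {
  driver_profile(gain_k = 0.05, noise_sigma = 0.10, lapse_rate = 2,
                 lapse_duration_mean = 4, lapse_bias = 0.2)
}

#' Simulation scenario
#'
#' @param duration Trace length, seconds.
#' @param dt Sampling interval, seconds (default 0.1).
#' @param alert,drowsy `driver_profile`s before and after the vigilance
#'   decay.
#' @param decay_onset Time at which vigilance starts to decay, s.  Set it
#'   equal to `duration` for a fully alert trace.
#' @param decay_ramp Length of the linear alert-to-drowsy transition, s.
#' @param seed Integer seed; identical seed and scenario give a
#'   bit-identical trace.
#' @param lane_half_width Lane half-width, m; `|lp|` beyond it is flagged
#'   as a lane departure (the trace continues).
#' @param lp0 Initial lateral position, m.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(duration, dt = 0.1, alert = alert_profile(),
                         drowsy = drowsy_profile(), decay_onset = duration,
                         decay_ramp = 0, seed = 1L, lane_half_width = 2,
                         lp0 = 0) {
  if (!(dt > 0 && dt < duration))
    lw_stop("need 0 < dt < duration", "lw_invalid_config")
  if (decay_onset < 0 || decay_ramp < 0 || decay_onset + decay_ramp > duration)
    lw_stop("need decay_onset >= 0, decay_ramp >= 0 and decay_onset + decay_ramp <= duration",
            "lw_invalid_config")
  for (p in list(alert, drowsy))
    if (!inherits(p, "driver_profile"))
      lw_stop("alert and drowsy must be driver_profile objects", "lw_invalid_config")
  structure(list(duration = duration, dt = dt, alert = alert, drowsy = drowsy,
                 decay_onset = decay_onset, decay_ramp = decay_ramp,
                 seed = as.integer(seed), lane_half_width = lane_half_width,
                 lp0 = lp0),
            class = "sim_scenario")
}

#' Convenience scenarios for detector evaluation
#'
#' `alert_scenario()` is a fully alert trace (no decay).
#' `decay_scenario()` degrades from the alert to the drowsy profile over a
#' ramp starting at `decay_onset`.
#'
#' @param duration,decay_onset,decay_ramp,seed See [sim_scenario()].
#' @param drowsy Drowsy-phase profile for the decay scenario.
#' @return A `sim_scenario`.
#' @export
alert_scenario <- function(duration = 1800, seed = 1L) {
  sim_scenario(duration = duration, decay_onset = duration, decay_ramp = 0,
               seed = seed)
}

#' @rdname alert_scenario
#' @export
decay_scenario <- function(duration = 2100, decay_onset = 1200,
                           decay_ramp = 300, drowsy = drowsy_profile(),
                           seed = 1L) {
  sim_scenario(duration = duration, decay_onset = decay_onset,
               decay_ramp = decay_ramp, drowsy = drowsy, seed = seed)
}

# Linear interpolation weight of the decay ramp at times t: 0 while alert,
# 1 once fully drowsy.  A zero-length ramp is a step at decay_onset.
ramp_weight <- function(t, onset, ramp) {
  if (ramp <= 0) as.numeric(t >= onset) else pmin(1, pmax(0, (t - onset) / ramp))
}

#' Simulate a lane-keeping trace
#'
#' Euler-Maruyama integration of the lateral position under the scenario's
#' time-varying driver profile.  Lapse onsets follow a Poisson process at
#' the current (interpolated) rate, with exponentially distributed
#' durations; during a lapse the corrective gain is zero and the vehicle
#' drifts at the lapse bias velocity.  The reported drift `lp_prime_cmps`
#' is the forward finite difference `(lp[i+1] - lp[i]) / dt * 100` (the
#' last sample repeats the previous value).
#'
#' @param sc A `sim_scenario`.
#' @return A list with elements:
#'   * `samples`: data frame `t` (s), `lp_m` (m), `lp_prime_cmps` (cm/s),
#'     `vigilance` (1 alert .. 0 drowsy), `in_lapse` (0/1),
#'     `departed` (0/1, `|lp| >` lane half-width);
#'   * `lapse_intervals`: data frame `start`, `end` (s);
#'   * `scenario`: the input scenario.
#' @export
#' @examples
#' tr <- simulate_trace(alert_scenario(duration = 60, seed = 7))
#' sd(tr$samples$lp_m)
simulate_trace <- function(sc) {
  if (!inherits(sc, "sim_scenario"))
    lw_stop("sc must be a sim_scenario", "lw_invalid_config")
  set.seed(sc$seed)
  dt <- sc$dt
  n <- as.integer(round(sc$duration / dt))
  t <- (seq_len(n) - 1) * dt
  w <- ramp_weight(t, sc$decay_onset, sc$decay_ramp)
  mix <- function(field) sc$alert[[field]] + (sc$drowsy[[field]] - sc$alert[[field]]) * w
  k_t <- mix("gain_k")
  sig_t <- mix("noise_sigma")
  rate_t <- mix("lapse_rate") / 60          # events/min -> events/s
  durm_t <- mix("lapse_duration_mean")
  bias_t <- mix("lapse_bias")

  eps <- stats::rnorm(n)
  u <- stats::runif(n)
  lp <- numeric(n)
  lp[1] <- sc$lp0
  in_lapse <- logical(n)
  lapse_end <- -Inf
  starts <- numeric(0); ends <- numeric(0)
  sqdt <- sqrt(dt)
  for (i in seq_len(n)) {
    lapsing <- t[i] < lapse_end
    if (!lapsing && u[i] < rate_t[i] * dt) {
      lapsing <- TRUE
      lapse_end <- t[i] + stats::rexp(1, rate = 1 / durm_t[i])
      starts <- c(starts, t[i]); ends <- c(ends, lapse_end)
    }
    in_lapse[i] <- lapsing
    if (i < n) {
      k_eff <- if (lapsing) 0 else k_t[i]
      b <- if (lapsing) bias_t[i] else 0
      lp[i + 1] <- lp[i] + dt * (-k_eff * lp[i] + b) + sig_t[i] * sqdt * eps[i]
    }
  }
  lp_prime <- c(diff(lp) / dt, NA) * 100
  if (n > 1) lp_prime[n] <- lp_prime[n - 1]
  samples <- data.frame(
    t = t, lp_m = lp, lp_prime_cmps = lp_prime,
    vigilance = 1 - w, in_lapse = as.integer(in_lapse),
    departed = as.integer(abs(lp) > sc$lane_half_width)
  )
  list(samples = samples,
       lapse_intervals = data.frame(start = starts,
                                    end = pmin(ends, sc$duration)),
       scenario = sc)
}

#' Monte-Carlo evaluation of the impairment detector
#'
#' Runs `simulate_trace -> judge_trace -> detect_impairment` over
#' `n_seeds` independent traces (seeds `sc$seed, sc$seed + 1, ...`) and
#' summarises detection performance.  A scenario whose `decay_onset`
#' equals its `duration` is treated as fully alert: every alarm it raises
#' is a false alarm.  For decay scenarios, detection latency is the time
#' from `decay_onset` to the first alarm at or after onset.
#'
#' @param sc A `sim_scenario`.
#' @param n_seeds Number of independent traces, at least 1.
#' @param config Pipeline configuration.
#' @return A list with `per_seed` (data frame: seed, n_alarms,
#'   first_alarm_t, latency), `sensitivity`, `false_alarm_rate`, and
#'   `latency_quantiles` (25/50/75%).
#' @export
evaluate_detector <- function(sc, n_seeds, config = default_config()) {
  if (!is.numeric(n_seeds) || n_seeds < 1)
    lw_stop("n_seeds must be at least 1", "lw_invalid_input")
  n_seeds <- as.integer(n_seeds)
  is_alert <- sc$decay_onset >= sc$duration
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    sci <- sc
    sci$seed <- (sc$seed + s - 1L) %% .Machine$integer.max
    tr <- simulate_trace(sci)
    jd <- judge_trace(tr$samples, config)
    al <- suppressWarnings(detect_impairment(jd, config))
    post <- al$t[al$t >= sc$decay_onset]
    rows[[s]] <- data.frame(
      seed = sci$seed, n_alarms = nrow(al),
      first_alarm_t = if (nrow(al)) min(al$t) else NA_real_,
      latency = if (!is_alert && length(post)) min(post) - sc$decay_onset
                else NA_real_
    )
  }
  per_seed <- do.call(rbind, rows)
  list(
    per_seed = per_seed,
    sensitivity = if (is_alert) NA_real_ else mean(!is.na(per_seed$latency)),
    false_alarm_rate = if (is_alert) mean(per_seed$n_alarms > 0)
                       else mean(!is.na(per_seed$first_alarm_t) &
                                 per_seed$first_alarm_t < sc$decay_onset),
    latency_quantiles = stats::quantile(per_seed$latency, c(0.25, 0.5, 0.75),
                                        na.rm = TRUE, names = TRUE)
  )
}

# Scenario from a configuration list (YAML/JSON `scenario:` block).
scenario_from_list <- function(spec) {
  prof <- function(block, fallback) {
    if (is.null(block)) return(fallback)
    do.call(driver_profile, utils::modifyList(unclass(fallback), block))
  }
  sim_scenario(
    duration = spec$duration %||% 1800,
    dt = spec$dt %||% 0.1,
    alert = prof(spec$alert_profile, alert_profile()),
    drowsy = prof(spec$drowsy_profile, drowsy_profile()),
    decay_onset = spec$decay_onset %||% (spec$duration %||% 1800),
    decay_ramp = spec$decay_ramp %||% 0,
    seed = spec$seed %||% 1L,
    lane_half_width = spec$lane_half_width %||% 2,
    lp0 = spec$lp0 %||% 0
  )
}
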