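---
title: "Scoring lane keeping and detecting drowsiness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lane keeping and detecting drowsiness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanewatch)
```

## The problem

Drowsiness degrades a driver's control of lateral position long before an
overt microsleep: corrective steering becomes slower and sloppier, the
vehicle wanders more widely in the lane, and eventually correction ceases
entirely for seconds at a time.  Lateral control is therefore a classical
non-intrusive performance marker of sleepiness (the standard deviation of
lateral position, SDLP, is its best-known summary).  lanewatch turns a
stream of lateral-position samples into a moment-by-moment driving-quality
score by fuzzy inference, learns each driver's alert score distribution,
and raises an alarm when the recent distribution deteriorates.

The two inputs are the lateral position LP (metres, signed offset of the
vehicle centre from the lane centre) and its first derivative LP'
(centimetres per second, the lateral drift velocity).  Both are taken
positive toward the right lane edge; sources that log drift positive
toward the left can set `lp_prime_sign: -1` in the configuration rather
than re-encode their files.  LP' needs a time base; this package uses
cm/s, which puts plausible highway drift magnitudes in the ±20 range the
partitions cover.

## The fuzzy inference system

Each input is fuzzified against five labelled sets — `Sx+` (very left),
`Sx` (left), `C` (central), `Dx` (right), `Dx+` (very right) — on a
bounded universe: ±2 m for LP, ±20 cm/s for LP'.  The exact membership
shapes are a design choice of this package: symmetric triangular Ruspini
partitions with peaks evenly spaced across the universe, end sets
shouldered at the edges.  This is the simplest family consistent with
five labelled sets on a symmetric bounded range, and it has two useful
consequences: membership degrees sum to exactly 1 everywhere (so every
crisp value activates at most two sets, and at most four rules ever
fire), and the partition is mirror-symmetric about the lane centre.
Inputs beyond the universe are clamped to the nearest bound before
evaluation: a vehicle 3 m off-centre is maximally "very right", and the
detector must keep scoring rather than halt.  Explicit breakpoints can be
supplied per label in the configuration to override the construction.

The rule base is a 5×5 matrix: *If LP is X and LP' is Y then J is Z*,
with judgments `Us+` (very unsafe), `Us`, `NSS` (not so safe), `S`, `S+`
(very safe).  Its governing principle: combinations that converge the
vehicle toward the lane centre are safe, combinations that diverge are
unsafe.  The default matrix (rows = LP, columns = LP', both ordered
`Sx+ … Dx+`):

```{r}
default_rule_matrix()
```

Three properties were imposed on the default entries.  First, point
symmetry — mirroring both inputs cannot change the judgment, matching the
mirror symmetry of the partitions.  Second, the anchor cells of the
convergence principle: centred and steady is `S+`, far off-centre and
diverging hard is `Us+`, offset with opposing drift is `S+`.  Third,
along the `Dx` row (offset 1 m right) the judgment is non-increasing as
drift runs from strongly corrective to strongly divergent; this forces
`(Dx, Sx+)` to `S+` rather than the more cautious `S` — under a pure
reading of "converging is safe", a strong correction at a moderate offset
is still fully safe.  An overshoot-penalising alternative (grading
`(Dx, Sx+)` as only `S`) is a one-line configuration override, at the
cost of a non-monotone row.

Activation is classic Mamdani: `min` for the rule AND, `max` to aggregate
rules sharing a conclusion.  The judgment universe 0–100 carries the same
Ruspini construction (peaks at 0, 25, 50, 75, 100).  Defuzzification is
centre of areas: each output set is clipped at its activation, the
pointwise-max envelope is formed on an evenly spaced grid (1001 points by
default, configurable), and the crisp score is the envelope centroid.
Both centroid sums are trapezoid-weighted; with plain end-point sums the
shouldered sets' edge mass gives a first-order grid error (~0.07 score
units at the default resolution), while trapezoidal weighting agrees with
a 10×-finer grid to better than 10⁻³.  The hot loop is compiled
(`src/coa.cpp`); 2×10⁵ samples score in about two seconds.

Two numerical consequences are worth knowing.  The score range is not the
full 0–100: a single fully activated shoulder set has centroid 275/3 ≈
91.67, so scores live in [8.33, 91.67] — the bounds of the scale are
approached, not attained, which is inherent to centroid defuzzification.
And the centroid of a *partially* clipped shoulder set moves with its
clip height (87.5 as the height tends to 0, rising to 91.67 at full
height), so along the `Dx` row the score dips by up to ~1.4 units and
recovers inside the `Sx+`/`Sx` crossfade even though both cells conclude
`S+`.  No assignment of the 25 cells removes this ripple under min/max
activation and envelope-centroid defuzzification; the monotone decline
is exact at the five pure drift labels and strict from the corrective
optimum (−10 cm/s) onward.

If no rule fires — impossible for finite inputs under clamping, but
reachable with user partitions that do not cover their universe — the
previous score is carried forward (or the neutral 50 at the start of a
trace) with a warning.

## Baseline learning and impairment detection

Judgment scores are appended to an in-memory record stream (with CSV
persistence).  The first `baseline_s` seconds (default 600) form the
driver's reference: a normalised 20-bin histogram over 0–100, kept
together with the raw baseline scores, usable once at least
`min_ref_samples` (100) records exist.  The baseline is assumed alert;
it is the "normal condition" the driver is compared against.

After the baseline, a comparison window of `window_s` seconds (default
600 — the last ten minutes of driving) slides along the stream with
stride `stride_s` (60 s).  Two detectors run at each position:

* **Distribution shift.**  Two-sample Kolmogorov–Smirnov statistic D
  between the reference scores and the window scores, against the
  asymptotic critical value `sqrt(-log(alpha/2)/2) * sqrt((n+m)/(nm))`.
  The alarm is one-sided in substance: it fires only if the window mean
  is *below* the reference mean.  An improving driver never alarms.
* **Negative trend.**  Ordinary least-squares slope of score against
  time, in score units per minute, gated at `slope_threshold` (−1/min),
  confirmed by a one-sided Mann–Kendall test (Kendall rank correlation
  of score with time) at level alpha.  The slope supplies magnitude, the
  rank test a distribution-free monotonicity decision; both must agree.

Two calibration choices keep the nominal level honest.  Scores arrive at
the trace rate (10 Hz) and are serially dependent at that timescale, so
both tests first thin to one score per `thin_s` seconds (default 2 s; at
that spacing the lag-1 autocorrelation of alert-trace scores is ≈ −0.03,
because the drift input is effectively white at the sampling rate).  And
`alpha` (0.05) is treated as a per-trace alarm budget: overlapping window
positions are not independent tests, so each test runs at the
Šidák-adjusted level `1 − (1 − alpha)^(1/K)` with K the number of
*non-overlapping* windows fitting the monitored span — the effective
number of independent looks.  On 100 simulated fully alert 30-minute
traces this yields a false-alarm fraction of 0.08, inside the 95%
binomial band of the nominal 0.05.  Each alarm kind has a refractory
period (300 s) to prevent alarm storms.  The detector contains no
randomness: a trace and a configuration always reproduce the same alarm
log.

## The lane-keeping simulator

No public corpus of drowsy lane-keeping traces accompanies this problem,
so the package ships a generative stand-in with ground truth.  The model
is a feedback-controlled driver: between lapses the lateral position
follows the Euler–Maruyama discretisation

lp[t+dt] = lp[t] + dt · (−k·lp[t] + b) + σ·√dt·ε,  ε ~ N(0,1),

an Ornstein–Uhlenbeck process with corrective gain `k` (1/s) and
perturbation scale `σ` (m/√s); its stationary spread is σ²/(2k), which
the tests use as a closed-form check.  Microsleep lapses arrive as a
Poisson process (rate in events/min), last exponentially long
(mean 4 s), and while they last the gain is zero and the vehicle drifts
at a constant bias velocity (0.2 m/s — a modest uncorrected heading
error).  Vigilance decay interpolates every profile parameter linearly
from an alert profile (k = 0.3/s, σ = 0.05, no lapses: stationary SDLP
≈ 0.065 m) to a drowsy one (k = 0.05/s, σ = 0.10, 2 lapses/min: SDLP
≈ 0.32 m plus lapse excursions) across a configurable ramp.  The
reported drift is the forward finite difference of the reported
position, in cm/s; at dt = 0.1 s its standard deviation is σ/√dt — about
16 cm/s when alert — so the drift input is noisy and nearly white, which
is what makes the judgment stream so weakly autocorrelated.

What the simulator emulates: the alert/drowsy contrast in lane-keeping
spread, progressive onset, and lapse-driven drift excursions — the
features the detector keys on.  What it does not: vehicle dynamics
(speed, curvature, tyres), steering-wheel and pedal signals, road
geometry, traffic, and any physiological channel.  Passing tests
therefore show that the detector recovers a known vigilance decay from
the lateral signal under this model; they do not certify performance on
real instrumented drives.

One seed drives a single generator stream per trace, so traces are
bit-reproducible; a lane departure (|lp| > 2 m) is flagged but the trace
continues, since the scorer clamps.

## Study conditions and measured performance

The evaluation scenarios are fixed: alert calibration uses 30-minute
fully alert traces; the decay scenario is 35 minutes with onset at 20
minutes and a 5-minute ramp (leaving a 10-minute fully drowsy tail); the
effect-size grid spans mild (k = 0.15, σ = 0.07, 0.5 lapses/min),
moderate (k = 0.10, σ = 0.085, 1/min) and severe (k = 0.05, σ = 0.10,
2/min) drowsy profiles.  With 100 seeds the decay scenario is detected
with sensitivity 1.0 at a median latency of 240 s from onset (within the
ramp), and median latency falls 420 → 300 → 240 s across the mild →
moderate → severe grid.  Problem sizes throughout (100 seeds for the
calibration and power runs, 30 per grid level, a 401×401 input grid for
the score-surface checks) were chosen so the whole evaluation re-runs in
a few minutes on one core while keeping binomial/Monte-Carlo error well
inside the asserted margins.

## Known limitations

* The rule matrix and membership shapes are principled defaults, not
  fits to human data; everything is overridable in YAML/JSON.
* The reference distribution assumes the baseline interval is alert; a
  driver who starts a session already impaired will poison the baseline
  and mute alarms.
* The KS critical value is asymptotic; with the default thinning a
  10-minute window contributes ~300 points, where the approximation is
  good, but very short windows would need an exact test.
* Detection latency is bounded below by the window having to accumulate
  degraded scores; a 10-minute window cannot flag a 30-second event.
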