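# lanewatch

Drowsiness degrades a driver's lateral control of the vehicle — lane
keeping gets sloppier, drift corrections come later, and microsleeps let
the car wander — well before the driver overtly falls asleep.  lanewatch
is an R toolkit for detecting that degradation from the lateral-position
signal alone.  It is aimed at driving-simulator and instrumented-vehicle
studies of sleepiness, fatigue and sedating-drug effects, where a
non-intrusive, continuously updated warning is wanted instead of a single
post-hoc index such as SDLP.

## What it computes

**Judgment score.**  At each time point the lateral position LP (m,
signed offset from the lane centre, positive rightward) and its
derivative LP′ (cm/s) are fuzzified against five triangular Ruspini sets
each (`Sx+ Sx C Dx Dx+` over ±2 m and ±20 cm/s), pushed through a 5×5
Mamdani rule matrix — *If LP is X and LP′ is Y then J is Z* with
judgments `Us+ Us NSS S S+`, safe where the inputs converge the vehicle
toward the lane centre, unsafe where they diverge — and defuzzified by
centre of areas (min/max activation, clipped-max envelope, trapezoidal
centroid on a 1001-point grid) to a crisp driving-quality score J on
0–100.

**Impairment alarms.**  Scores from the first 10 minutes form the
driver's alert reference distribution.  A 10-minute window then slides
along the score stream and raises an alarm when (a) a one-sided
two-sample Kolmogorov–Smirnov comparison shows the window distribution
shifted below the reference, or (b) the window score trend is steeper
than −1 point/min with a Mann–Kendall confirmation.  The configured
α = 0.05 is a per-trace alarm budget (Šidák-split over the effective
number of independent windows), and both tests thin the scores to one
per 2 s to respect serial dependence.

**Simulator.**  A lane-keeping generator with ground truth: an
Ornstein–Uhlenbeck feedback driver whose corrective gain, noise and
microsleep lapse rate interpolate from an alert to a drowsy profile
across a vigilance-decay ramp.  It provides every test input and the
Monte-Carlo harness (`evaluate_detector()`) for sensitivity, latency and
false-alarm measurement.

## Worked example

```r
library(lanewatch)

# one sample: 0.6 m right of centre, drifting right at 8 cm/s
judge(list(t = 0, lp_m = 0.6, lp_prime_cmps = 8))
#> <judgment_record> t = 0 s, score = 47.38 (4 rules fired)
```

The score 47.38 sits just below "not so safe" (50): the vehicle is
moderately offset and still drifting away from the centre.  Four rules
fire — the sample has partial membership in `C`/`Dx` and in `C`/`Dx`
drift — the strongest being *If LP is Dx and LP′ is Dx then J is Us* at
0.6.

```r
# 35-minute trace: alert for 20 min, then a 5-min decay into drowsiness
tr <- simulate_trace(decay_scenario(seed = 42))
jd <- judge_trace(tr$samples)      # 21,000 judgments in ~0.3 s
detect_impairment(jd)
#>      t               kind  statistic  threshold window_start window_end
#> 1 1320 distribution_shift  0.1266667  0.1206826          720       1320
#> 2 1440     negative_trend -1.0381238 -1.0000000          840       1440
#> 3 1620 distribution_shift  0.2066667  0.1206826         1020       1620
#> 4 1740     negative_trend -1.2308221 -1.0000000         1140       1740
#> 5 1920 distribution_shift  0.2900000  0.1206826         1320       1920
```

Vigilance decay starts at t = 1200 s; the first alarm lands at
t = 1320 s — 120 s after onset, mid-ramp — and both alarm kinds recur
(subject to the 5-min refractory period) as the driver's mean score
falls from 66 during the baseline to 53 in the final ten minutes.

A command-line wrapper covers the same pipeline for batch use
(`exec/lanewatch` after installation):

```sh
lanewatch simulate --config inst/extdata/decay_scenario.yaml --out trace.csv
lanewatch monitor  --trace trace.csv --out judgments.csv --alarms alarms.csv
lanewatch evaluate --config inst/extdata/decay_scenario.yaml --n-seeds 20 --out metrics.csv
```

All thresholds, partitions and the rule matrix are overridable from a
YAML/JSON configuration; `inst/extdata/default_config.yaml` documents
every default.  See `vignettes/lanewatch-methods.Rmd` for the model,
its assumptions and the calibration choices.

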