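# lanewatch default configuration.  Every value here equals the built-in
# default; edit a copy to override partitions, rules or thresholds.
partitions:
  lp:            # lateral position, metres, positive toward the right edge
    lo: -2
    hi: 2
    labels: ["Sx+", "Sx", "C", "Dx", "Dx+"]
  lp_prime:      # lateral drift, cm/s, positive toward the right edge
    lo: -20
    hi: 20
    labels: ["Sx+", "Sx", "C", "Dx", "Dx+"]
  judgment:      # driving-quality score
    lo: 0
    hi: 100
    labels: ["Us+", "Us", "NSS", "S", "S+"]
rules:           # rows keyed by LP label; one output per LP' label, in order
  "Sx+": ["Us+", "Us+", "Us", "NSS", "S"]
  "Sx":  ["Us+", "Us", "NSS", "S+", "S+"]
  "C":   ["NSS", "S", "S+", "S", "NSS"]
  "Dx":  ["S+", "S+", "NSS", "Us", "Us+"]
  "Dx+": ["S", "NSS", "Us", "Us+", "Us+"]
defuzz_resolution: 1001
lp_prime_sign: 1          # set to -1 if the source logs drift positive-left
monitoring:
  alpha: 0.05             # per-trace alarm budget
  bins: 20                # reference histogram bins over [0, 100]
  baseline_s: 600         # reference-learning interval
  window_s: 600           # comparison window (last 10 minutes)
  stride_s: 60            # window stride
  thin_s: 2               # score thinning before the statistical tests
  slope_threshold: -1     # score units per minute
  trend_min_points: 30
  refractory_s: 300       # minimum spacing between alarms of one kind
  min_ref_samples: 100
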