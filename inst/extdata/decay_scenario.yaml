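# Vigilance-decay evaluation scenario: 35 minutes of driving, alert for the
# first 20, then a 5-minute ramp into the drowsy profile.
scenario:
  duration: 2100
  dt: 0.1
  decay_onset: 1200
  decay_ramp: 300
  seed: 1
  alert_profile:  {gain_k: 0.3,  noise_sigma: 0.05, lapse_rate: 0}
  drowsy_profile: {gain_k: 0.05, noise_sigma: 0.10, lapse_rate: 2,
                   lapse_duration_mean: 4, lapse_bias: 0.2}
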