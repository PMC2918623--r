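# Example override configuration for the closed-loop simulator.
# Any key omitted here falls back to the documented defaults
# (aiis_defaults()); an empty file reproduces them exactly.
patient:
  body_weight: 70      # kg
  Sh: 0.5              # hepatic insulin sensitivity
sensor:
  noise_variance: 100  # nA^2 per raw 10-s sample
scenario:
  kind: severe         # mild | moderate | severe | negative
  challenge_time: 600  # minutes (hour 10:00)
  duration: 1440       # minutes
seed: 1
output_dir: aiis-run
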