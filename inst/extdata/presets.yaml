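# Experiment presets for the four FPVS face-regularity designs.
# Rates in Hz, durations in seconds, intervals in msec.
pilot1:
  stimulation_rate: 15
  regularity_divisor: 3
  trial_duration: 3.8
  refresh_rate: 60
  orientations: [upright, inverted]
  regularities: [angry, neutral, irregular]
  variabilities: [none]
  trials_per_condition: 96
  expressions: [angry, neutral, happy]
  filler_only: [happy]
  identities:
    none: [id21, id22, id23, id25, id26, id33, id34, id36, id37]
  target_policy:
    target_trials_per_condition: 36
    max_targets_per_trial: 3
    min_target_interval: 600
    target_duration_frames: 2
pilot2:
  stimulation_rate: 15
  regularity_divisor: 3
  trial_duration: 3.8
  refresh_rate: 60
  orientations: [upright, inverted]
  regularities: [angry, neutral, irregular]
  variabilities: [high, low]
  trials_per_condition: 48
  expressions: [angry, neutral, happy, disgusted]
  filler_only: [happy, disgusted]
  identities:
    high: [id37]
    low: [id06]
  target_policy:
    target_trials_per_condition: 18
    max_targets_per_trial: 3
    min_target_interval: 600
    target_duration_frames: 2
exp1:
  stimulation_rate: 6
  regularity_divisor: 3
  trial_duration: 7
  refresh_rate: 60
  orientations: [upright, inverted]
  regularities: [angry, neutral, irregular]
  variabilities: [high, low]
  trials_per_condition: 48
  expressions: [angry, neutral, happy, disgusted]
  filler_only: [happy, disgusted]
  identities:
    high: [id37]
    low: [id06]
  target_policy:
    target_trials_per_condition: 18
    max_targets_per_trial: 3
    min_target_interval: 800
    target_duration_frames: 2
exp2:
  stimulation_rate: 6
  regularity_divisor: 3
  trial_duration: 7
  refresh_rate: 60
  orientations: [upright, inverted]
  regularities: [angry, neutral, irregular]
  variabilities: [high, low]
  trials_per_condition: 30
  expressions: [angry, neutral, happy, disgusted]
  filler_only: [happy, disgusted]
  identities:
    high: [id37]
    low: [id06]
  target_policy: ~
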