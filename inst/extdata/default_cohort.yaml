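# Default generative parameters for the synthetic screening cohort.
#
# The two groups encode the qualitative contrast seen in reconstructed
# traces of real sessions: PD-like participants trace faster but with
# pronounced oscillatory deviation and jitter, respond more slowly and
# more variably to key prompts, and produce more false presses. Values are
# chosen for clear group separability; they are NOT calibrated to any real
# cohort (no per-group deviation/timing summaries are publicly available).
screen:
  width: 1280
  height: 800
sampling_interval: 500    # ms between mouse samples
keyboard:
  timeout_ms: 5000        # prompt window length
  constant_key: f
  alternating_keys: [f, j]
pd:
  tremor_amplitude: 12    # px, oscillatory deviation along the path normal
  tremor_freq: 5          # Hz (rest-tremor band; aliased by 500 ms sampling)
  jitter_sd: 3            # px, white positional noise
  trace_speed: 0.12       # fraction of path length per second (faster)
  speed_cv: 0.35          # log-scale SD of per-trial speed
  rt_log_mean: 6.551      # log-ms; exp() ~ 700 ms median response time
  rt_log_sd: 0.45
  false_press_rate: 0.6   # expected false presses per prompt
  timeout_prob: 0.08      # probability a prompt goes unresolved
control:
  tremor_amplitude: 2
  tremor_freq: 5
  jitter_sd: 1
  trace_speed: 0.08       # slower but more precise
  speed_cv: 0.2
  rt_log_mean: 6.109      # exp() ~ 450 ms median response time
  rt_log_sd: 0.25
  false_press_rate: 0.05
  timeout_prob: 0.01
# Demographic marginals per group (cosmetic; no effect on motor generation).
# Age-bracket weights follow the published cohort's distribution.
demographics:
  age_brackets: ["40-49", "50-59", "60-69", "70-79", "80-90"]
  pd:
    age_weights: [0, 2, 4, 7, 0]
    gender_weights: {male: 8, female: 5}
    race_weights: {white: 10, asian: 3, american_indian_alaska_native: 0, unspecified: 0}
  control:
    age_weights: [3, 4, 5, 5, 1]
    gender_weights: {male: 7, female: 11}
    race_weights: {white: 8, asian: 8, american_indian_alaska_native: 1, unspecified: 1}
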