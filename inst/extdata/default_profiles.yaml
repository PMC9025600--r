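# Default response profiles for the six-sensor metal-oxide panel.
# Voltages in volts (ADC range 0-3.3 V), time constants in seconds.
# Plateau means rise with grade (decayed fruit emits more volatiles), with
# sensor-specific separations; overshoot is enabled on two sensors so the
# per-sensor maximum feature is not degenerate with the stable feature.
# MQ-8 and MQ-6 are modeled as cross-sensitivity dominated: little or no
# grade signal but large sample-to-sample variance, as real MOS panels show
# for sensors whose target gases the fruit barely emits.
# These values are synthetic: the study's recordings were never deposited,
# so the table stipulates a realistic panel rather than a fitted one.
sensors:
  - sensor: MQ-9
    baseline_v: 0.60
    plateau_mean: {L1: 1.40, L2: 1.65, L3: 1.95}
    plateau_sd: 0.11
    rise_tau: 4.0
    overshoot_frac: 0.0
    overshoot_decay_tau: 15.0
    noise_sd: 0.02
  - sensor: MQ-3
    baseline_v: 0.50
    plateau_mean: {L1: 1.20, L2: 1.55, L3: 1.90}
    plateau_sd: 0.13
    rise_tau: 5.0
    overshoot_frac: 0.25
    overshoot_decay_tau: 18.0
    noise_sd: 0.02
  - sensor: MQ-6
    baseline_v: 0.55
    plateau_mean: {L1: 1.10, L2: 1.16, L3: 1.24}
    plateau_sd: 0.25
    rise_tau: 6.0
    overshoot_frac: 0.0
    overshoot_decay_tau: 15.0
    noise_sd: 0.02
  - sensor: MQ-8
    baseline_v: 0.45
    plateau_mean: {L1: 1.00, L2: 1.00, L3: 1.00}
    plateau_sd: 0.30
    rise_tau: 5.0
    overshoot_frac: 0.20
    overshoot_decay_tau: 15.0
    noise_sd: 0.02
  - sensor: MQ-2
    baseline_v: 0.70
    plateau_mean: {L1: 1.60, L2: 1.80, L3: 2.05}
    plateau_sd: 0.13
    rise_tau: 4.0
    overshoot_frac: 0.0
    overshoot_decay_tau: 15.0
    noise_sd: 0.02
  - sensor: MQ-135
    baseline_v: 0.65
    plateau_mean: {L1: 1.30, L2: 1.60, L3: 1.95}
    plateau_sd: 0.13
    rise_tau: 5.0
    overshoot_frac: 0.0
    overshoot_decay_tau: 15.0
    noise_sd: 0.02
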