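# Base-case model configuration. Probabilities/utilities are fractions
# (set `probability_units: percent` to supply percentages instead).
probability_units: fraction
pretest_prob: 0.02635
start_age: 60
horizon_cycles: 20
discount_rate: 0.03
wtp: 100000
cost_fp_followup: 2256
cost_resection: 36305
cost_post_resection_annual: 4283
cost_palliative_annual: 60000
cost_undetected: 0
utility_no_bc: 1
utility_fp: 0.98
utility_resection_year1: 0.79
utility_post_resection: 0.933
utility_undetected: 1
utility_palliative: 0.63
utility_dead: 0
p_resect_early: 0.75
p_resect_delayed: 0.26
p_death_post_resection: 0.047
p_recurrence: 0.098
p_death_palliative: 0.36
p_death_fp_procedural: 0.001
detection_schedule: [0.15, 0.40, 1.00]
p_verify_fp_as_no_bc: 1.0
strategies:
  ct:
    sensitivity: 0.779
    specificity: 0.877
    screen_cost: 161
    ai_cost: 0
  ct_ai:
    sensitivity: 0.977
    specificity: 0.984
    screen_cost: 161
    ai_cost: 0
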