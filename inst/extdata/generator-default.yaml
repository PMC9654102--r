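# Default latent-severity generator parameters.
# Qualitative calibration: threshold ordering b1 < b3 < b2 < b4 = b5 = b7
# < b6 < b8 < b9 = b10 reproduces the canonical affirmation ordering among
# food-insecure households; the overall 10-item food-insecurity prevalence
# lands in the 10-20% band with the reference (>= 3 affirmations)
# prevalence near 6%, and the low-income / welfare / not-living-with-spouse
# subgroups carry elevated severity.  Not a fit to any survey dataset.
mu: -2.2
sigma: 1.0
discrimination: 3.0
thresholds:
  - 0.00    # q1 worried food would run out
  - 0.50    # q2 food bought didn't last
  - 0.20    # q3 couldn't afford balanced meals
  - 1.10    # q4 cut or skipped meals
  - 1.10    # q5 how often (follow-up of q4)
  - 1.35    # q6 ate less than felt should
  - 1.10    # q7 hungry but didn't eat
  - 2.20    # q8 lost weight
  - 2.60    # q9 whole day without eating
  - 2.60    # q10 how often (follow-up of q9)
single_item_threshold: 0.65
often_shift: 0.9
covariate_prevalence:
  has_children: 0.35
  highschool_or_diploma: 0.35
  not_living_with_spouse: 0.15
  income_under_70000: 0.25
  welfare_recipient: 0.13
covariate_effect:
  has_children: 0.15
  highschool_or_diploma: 0.35
  not_living_with_spouse: 0.65
  income_under_70000: 1.25
  welfare_recipient: 0.85
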