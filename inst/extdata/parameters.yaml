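# Canonical model inputs for the low-intensity CBT cost-effectiveness model.
# This file is the single source of the default parameter set.  Event rates
# printed as percentages in the source material are stored here as fractions;
# money is in US dollars; time is in months unless stated otherwise.
# dist: distribution family used in probabilistic sensitivity analysis.
#   beta / gamma are fitted by method of moments with mean = base and
#   sd = (high - low) / 3.92; triangular uses (min = low, mode = base,
#   max = high); fixed parameters are never sampled.

recovery_low_cbt:
  base: 0.639
  low: 0.511
  high: 0.767
  dist: beta
  scale: probability
  units: probability per program
  label: Recovery to well after low-intensity CBT, mild symptoms

deterioration_low_cbt:
  base: 0.053
  low: 0.042
  high: 0.064
  dist: beta
  scale: probability
  units: probability per program
  label: Deterioration to moderate-severe symptoms after low-intensity CBT

rel_effect_internet:
  base: 1.00
  low: 0.95
  high: 1.05
  dist: triangular
  scale: multiplier
  units: ratio
  label: Relative effectiveness, internet-based vs in-person CBT

recovery_none:
  base: 0.25
  low: 0.20
  high: 0.30
  dist: beta
  scale: probability
  units: probability per program window
  label: Spontaneous recovery to well, no intervention

deterioration_none:
  base: 0.091
  low: 0.073
  high: 0.109
  dist: beta
  scale: probability
  units: probability per program window
  label: Deterioration to moderate-severe symptoms, no intervention

accept_inperson:
  base: 0.633
  low: 0.601
  high: 0.665
  dist: beta
  scale: probability
  units: probability
  label: Acceptance of in-person CBT

accept_internet:
  base: 0.753
  low: 0.715
  high: 0.791
  dist: beta
  scale: probability
  units: probability
  label: Acceptance of internet-based CBT

comply_inperson:
  base: 0.839
  low: 0.757
  high: 0.921
  dist: beta
  scale: probability
  units: probability
  label: Compliance with in-person CBT

comply_internet:
  base: 0.808
  low: 0.730
  high: 0.887
  dist: beta
  scale: probability
  units: probability
  label: Compliance with internet-based CBT

mortality_monthly:
  base: 0.000025
  low: 0.000020
  high: 0.000030
  dist: beta
  scale: probability
  units: probability per month
  label: Age-specific all-cause mortality

rr_mortality_depressed:
  base: 1.81
  low: 1.58
  high: 2.07
  dist: triangular
  scale: multiplier
  units: ratio
  label: Relative risk of mortality with depressive symptoms

remission_monthly:
  base: 0.0054
  low: 0.0043
  high: 0.0065
  dist: beta
  scale: probability
  units: probability per month
  label: Remission from depressive symptoms

relapse_monthly:
  base: 0.0244
  low: 0.0195
  high: 0.0293
  dist: beta
  scale: probability
  units: probability per month
  label: Relapse from well/remission

prop_mild_relapse:
  base: 0.243
  low: 0.192
  high: 0.288
  dist: beta
  scale: proportion
  units: proportion
  label: Proportion of mild symptoms among relapses

prop_moderate_among_modsev:
  base: 0.50
  low: 0.40
  high: 0.60
  dist: beta
  scale: proportion
  units: proportion
  label: Proportion of moderate symptoms among moderate-severe cases

hosp_monthly_severe:
  base: 0.0178
  low: 0.0142
  high: 0.0214
  dist: beta
  scale: probability
  units: probability per month
  label: Psychiatric hospitalization among severe cases

dropout_monthly_well:
  base: 0.00124
  low: 0.00099
  high: 0.00149
  dist: beta
  scale: probability
  units: probability per month
  label: School dropout, well/remission

dropout_monthly_dep:
  base: 0.00193
  low: 0.00154
  high: 0.00232
  dist: beta
  scale: probability
  units: probability per month
  label: School dropout, depressive symptoms

age:
  base: 21
  low: 20
  high: 22
  dist: triangular
  scale: count
  units: years
  label: Cohort age at entry

utility_age:
  base: 0.92
  dist: fixed
  scale: utility
  units: utility
  label: Age-specific utility (documented alternative for the well state)

utility_remission:
  base: 0.80
  low: 0.72
  high: 0.88
  dist: triangular
  scale: utility
  units: utility
  label: Utility, well/remission

utility_mild:
  base: 0.62
  low: 0.56
  high: 0.68
  dist: triangular
  scale: utility
  units: utility
  label: Utility, mild depressive symptoms

utility_moderate:
  base: 0.48
  low: 0.43
  high: 0.53
  dist: triangular
  scale: utility
  units: utility
  label: Utility, moderate depressive symptoms

utility_severe:
  base: 0.33
  low: 0.30
  high: 0.36
  dist: triangular
  scale: utility
  units: utility
  label: Utility, severe depressive symptoms

sessions_low:
  base: 7
  low: 6
  high: 8
  dist: triangular
  scale: count
  units: sessions per course
  label: Low-intensity CBT, number of sessions

minutes_low:
  base: 30
  dist: fixed
  scale: count
  units: minutes per session
  label: Low-intensity CBT, session duration

sessions_high:
  base: 18
  low: 16
  high: 20
  dist: triangular
  scale: count
  units: sessions per course
  label: High-intensity CBT, number of sessions

minutes_high:
  base: 60
  dist: fixed
  scale: count
  units: minutes per session
  label: High-intensity CBT, session duration

therapist_hourly:
  base: 54
  low: 43
  high: 62
  dist: triangular
  scale: money
  units: US $ per hour
  label: Psychotherapist service per hour

platform_overhead:
  base: 24
  low: 20
  high: 29
  dist: triangular
  scale: money
  units: US $ per participant
  label: Platform overhead for internet-based CBT

therapist_time_share_internet:
  base: 0.0923
  low: 0.0738
  high: 0.111
  dist: beta
  scale: proportion
  units: proportion of in-person therapist time
  label: Therapist time share, guided internet-based CBT

outpatient_monthly:
  base: 231
  low: 160
  high: 335
  dist: gamma
  scale: money
  units: US $ per patient-month
  label: Psychiatric outpatient care

hosp_episode_cost:
  base: 1500
  low: 900
  high: 2100
  dist: gamma
  scale: money
  units: US $ per episode
  label: Psychiatric hospitalization

horizon_months:
  base: 60
  dist: fixed
  scale: count
  units: months
  label: Model time horizon

cycle_months:
  base: 1
  dist: fixed
  scale: count
  units: months
  label: Markov cycle length

discount_annual:
  base: 0.03
  dist: fixed
  scale: proportion
  units: annual rate
  label: Discounting rate for costs and QALYs

wtp:
  base: 48119
  dist: fixed
  scale: money
  units: US $ per QALY
  label: Willingness-to-pay threshold (GDP per capita)
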