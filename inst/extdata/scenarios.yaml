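# Default univariate sensitivity scenarios: each entry overrides one or more
# named configuration parameters (dot-separated paths). Mirrors
# diadem::default_scenarios().
relapse_time_2yr:
  natural_history.mean_time_relapse: 2
relapse_time_1yr:
  natural_history.mean_time_relapse: 1
hr_comp_on_dep_1.0:
  natural_history.hr_complication_on_depression: 1.0
hr_comp_on_dep_2.0:
  natural_history.hr_complication_on_depression: 2.0
hr_dep_on_comp_null:
  complications.hr_depression.micro.minor: 1
  complications.hr_depression.micro.major: 1
  complications.hr_depression.macro.minor: 1
  complications.hr_depression.macro.major: 1
major_disutility_0.2:
  utilities.depression.major: -0.2
major_disutility_0.4:
  utilities.depression.major: -0.4
screen_cost_0:
  costs.opportunistic_screen: 0
screen_cost_4:
  costs.opportunistic_screen: 4
cc_cost_half:
  treatment.cc_extra_cost: 90
cc_cost_double:
  treatment.cc_extra_cost: 360
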