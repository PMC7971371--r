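# Zanzibar community health volunteer (CHV) quantification: 1,579,849 total
# population (268,574 children under 5; 2018 official statistics), and the
# adopted answer of 2,200 CHVs working at most 18 hours per week, travel
# occupying one third of available time, each serving approximately 720
# persons, targeting 90% coverage of the adopted package. The detailed
# intervention catalog (frequencies, durations) was not published, so this
# fixture ships without one; an illustrative (clearly invented) catalog
# appears in the package vignette.
schema_version: 1
name: zanzibar
allocation_mode: proportional
profile:
  name: zanzibar
  total_population: 1579849
  group_counts:
    under-5: 268574
cadres:
- name: chv
  headcount: 2200
  time_policy:
    hours_per_week: 18
    weeks_per_year: 52
    travel_share: 0.3333333333333333
interventions: []
known_values:
  total_population:
    value: 1579849
    source: Zanzibar official statistics, 2018
  under_5_population:
    value: 268574
    source: Zanzibar official statistics, 2018
  chvs:
    value: 2200
    source: adopted CHV headcount, updated national community health strategy
  hours_per_week:
    value: 18
    source: maximum CHV time commitment, updated national community health strategy
  travel_share:
    value: 0.3333333333333333
    source: travel reported to occupy one third of CHV available time
  persons_per_chv:
    value: 720
    source: approximate persons served per CHV (total population / 2,200, nearest ten)
  package_coverage_goal:
    value: 0.9
    source: targeted coverage of the adopted CHV service package
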