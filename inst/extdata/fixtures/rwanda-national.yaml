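# Rwanda national program: reported cadre headcounts (15,361 ASMs, 29,314
# binomes, 13,892 HP-CHWs; 58,567 CHWs in all) serving 12.37 million people
# (2019 estimate). National intervention catalogs were not published; the
# HP-CHW workload uses the same SYNTHETIC ENCODING of reported per-CHW
# aggregates as the typology fixtures.
schema_version: 1
name: rwanda-national
allocation_mode: proportional
profile:
  name: rwanda-national
  total_population: 12370000
  group_counts:
    hp-chw-workload-units: 13892
cadres:
- name: asm
  headcount: 15361
  time_policy:
    hours_per_week: 15.8
    weeks_per_year: 40
- name: binome
  headcount: 29314
  time_policy:
    hours_per_week: 15.8
    weeks_per_year: 40
- name: hp-chw
  headcount: 13892
  time_policy:
    hours_per_week: 15.8
    weeks_per_year: 40
interventions:
- name: hp-chw-assigned-workload
  cadre: hp-chw
  mode: home-visit
  target:
    kind: stock-group
    key: hp-chw-workload-units
  contacts_per_year: 1300
  minutes_per_contact: 60
  coverage_goal: 1
known_values:
  total_population:
    value: 12370000
    source: Rwanda program, total population served (2019 estimate)
  asms:
    value: 15361
    source: Rwanda program, reported national cadre headcounts
  binomes:
    value: 29314
    source: Rwanda program, reported national cadre headcounts
  hp_chws:
    value: 13892
    source: Rwanda program, reported national cadre headcounts
  total_chws:
    value: 58567
    source: Rwanda program, reported national CHW total
  hp_chw_demand_hours_per_chw:
    value: 1300
    source: reported aggregate, annual hours needed per HP-CHW (synthetic encoding)
  hp_chw_available_hours_per_chw:
    value: 632
    source: reported aggregate, annual hours available per HP-CHW (synthetic encoding)
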