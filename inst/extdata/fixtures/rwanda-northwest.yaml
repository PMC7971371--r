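# Rwanda, Rural Northern and Western (lower-malaria) typology.
# Same encoding conventions as rwanda-eastern.yaml: published population and
# cadre headcounts; HP-CHW workload is a SYNTHETIC ENCODING of the reported
# per-CHW aggregates (1,300 h demanded vs 632 h available, reported for both
# typologies with only minor unpublished differences).
schema_version: 1
name: rwanda-northwest
allocation_mode: proportional
profile:
  name: rwanda-northwest
  total_population: 2178695
  group_counts:
    under-5: 286259
    hp-chw-workload-units: 3392
cadres:
- name: asm
  headcount: 3456
  time_policy:
    hours_per_week: 15.8
    weeks_per_year: 40
- name: binome
  headcount: 6949
  time_policy:
    hours_per_week: 15.8
    weeks_per_year: 40
- name: hp-chw
  headcount: 3392
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
    value: 2178695
    source: Rwanda program typology assumptions (2012 census basis)
  under_5_population:
    value: 286259
    source: Rwanda program typology assumptions (2012 census basis)
  asms:
    value: 3456
    source: Rwanda program typology assumptions, cadre headcounts
  binomes:
    value: 6949
    source: Rwanda program typology assumptions, cadre headcounts
  hp_chws:
    value: 3392
    source: Rwanda program typology assumptions, cadre headcounts
  population_per_all_chws:
    value: 158
    source: Rwanda program typology assumptions, population per all CHWs
  hp_chw_demand_hours_per_chw:
    value: 1300
    source: reported aggregate, annual hours needed per HP-CHW (synthetic encoding)
  hp_chw_available_hours_per_chw:
    value: 632
    source: reported aggregate, annual hours available per HP-CHW (synthetic encoding)
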