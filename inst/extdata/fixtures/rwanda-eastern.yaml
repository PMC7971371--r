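# Rwanda, Rural Eastern (higher-malaria) typology.
# Population, under-5 count, and cadre headcounts are the published program
# assumptions (2012 census basis). Intervention-level inputs (durations,
# frequencies) were never published; the HP-CHW workload is therefore a
# SYNTHETIC ENCODING of the reported per-CHW aggregates: 1,300 demanded and
# 632 available service hours per HP-CHW per year. One "workload unit" per
# HP-CHW receives 1,300 one-hour contacts annually, and the time policy is
# tuned so that 15.8 h/wk x 40 wk = 632 service h/yr. ASM and binome cadres
# carry headcounts only (their catalogs were not published); they share the
# placeholder time policy.
schema_version: 1
name: rwanda-eastern
allocation_mode: proportional
profile:
  name: rwanda-eastern
  total_population: 2600814
  group_counts:
    under-5: 338106
    hp-chw-workload-units: 3837
cadres:
- name: asm
  headcount: 3794
  time_policy:
    hours_per_week: 15.8
    weeks_per_year: 40
- name: binome
  headcount: 7799
  time_policy:
    hours_per_week: 15.8
    weeks_per_year: 40
- name: hp-chw
  headcount: 3837
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
    value: 2600814
    source: Rwanda program typology assumptions (2012 census basis)
  under_5_population:
    value: 338106
    source: Rwanda program typology assumptions (2012 census basis)
  asms:
    value: 3794
    source: Rwanda program typology assumptions, cadre headcounts
  binomes:
    value: 7799
    source: Rwanda program typology assumptions, cadre headcounts
  hp_chws:
    value: 3837
    source: Rwanda program typology assumptions, cadre headcounts
  population_per_all_chws:
    value: 169
    source: Rwanda program typology assumptions, population per all CHWs
  hp_chw_demand_hours_per_chw:
    value: 1300
    source: reported aggregate, annual hours needed per HP-CHW (synthetic encoding)
  hp_chw_available_hours_per_chw:
    value: 632
    source: reported aggregate, annual hours available per HP-CHW (synthetic encoding)
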