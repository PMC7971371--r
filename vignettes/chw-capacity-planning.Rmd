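---
title: "Time-use modeling of CHW coverage and capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-use modeling of CHW coverage and capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chwplan)
```

## The planning problem

Community health worker (CHW) programs assign a package of promotive,
preventive, and curative services to one or more cadres of lay workers.
Each service prescribes a target population, a contact frequency, a
duration, and a coverage goal; each cadre has a headcount and a weekly time
commitment of which only part is available for direct service delivery.
`chwplan` does the resulting time-use accounting and answers three
questions: the headcount needed for full coverage, the coverage achievable
by a fixed workforce, and how what-if edits move the balance.

The model is a deterministic annual snapshot. It deliberately excludes
costing, supervision networks, multi-year population projection,
within-year seasonality, attrition, and stochastic workload — a planning
year is modeled with the year's totals.

## Demand side

An intervention's target population is sized from a population profile:

* a **stock group** (e.g. children under 5) as
  `total_population × group_fraction`;
* an **annual event stream** (e.g. live births) as
  `total_population × events per person-year`.

Both are scaled by an **in-need fraction** — the epidemiological share of
the group actually requiring the service (in `[0, 1]`; caseload multipliers
above one, such as repeat illness episodes, belong in the contact
frequency) — and reduced by a **facility share**, the portion expected to be
served at health facilities rather than in the community. Profiles take
fractions/rates or raw counts (counts are stored as `count/total`, so they
round-trip exactly); all demographic indicators are user inputs — the
package never derives or downloads them.

Annual demand in hours is then
`target × goal × contacts_per_year × minutes / 60`. Group sessions divide
the contact count by the group size — exactly by default, because at
program scale the whole-session correction is negligible and exact division
keeps demand linear in every parameter (which the property tests exploit);
a `group_rounding = "ceiling"` variant batches whole sessions. Counts stay
fractional throughout; only reported headcounts are integers, which avoids
compounding rounding across a catalog.

## Supply side

A cadre's time policy nets annual service time out of gross working time:

```
service = (hours_per_week × weeks_per_year − training_h − campaign_h)
          × (1 − travel_share − admin_share)
```

Block commitments (annual training hours, campaign/ad-hoc hours) come off
first; travel and administration are shares of the remaining working time.
Two conventions deserve note:

* **Travel as a share.** The one quantitative travel figure from fielded
  programs is a share of available time (one third for Zanzibar's
  volunteers), so the share form is the default. A per-visit travel
  surcharge (`travel_minutes_per_contact`) exists for catalogs parameterized
  that way — use one or the other for the same travel, not both.
* **Campaigns as block time.** Campaign frequency is typically decided per
  program unit, not per target individual, so campaigns are hours per CHW
  per year in the time policy rather than a per-contact intervention.
  (Training is likewise subtracted as hours, not weeks.)
* **`weeks_per_year` defaults to 48** — a full year minus leave. No
  published program states this value, so it is explicit, documented, and
  overridable; the Zanzibar fixture uses 52 because its 18 hours/week cap is
  quoted on a whole-year basis.

## The three questions

**Q1, staffing.** Per cadre, `ceil(Σ demand / service hours per CHW)`. The
ceiling is taken once at program level; per-catchment granularity is better
read from the population-per-CHW ratio (`population_per_chw()`), the
convention used in program assumption tables. A guard subtracts 10⁻⁹ before
the ceiling so that demand equal to an exact multiple of per-CHW supply
does not gain a spurious extra worker from floating-point noise.

**Q2, coverage.** Per cadre, supply is `headcount × service hours`; the
aggregate achievable share is `min(1, supply/demand)`. When a cadre is
overloaded, hours are rationed by one of two first-class allocation rules:

* `proportional` (default): every intervention achieves the same fraction
  `supply/demand` of its goal. This matches how fielded analyses summarize
  overload ("under half of the assigned workload").
* `priority-fill`: interventions are filled completely in priority order
  until supply runs out — the arithmetic of deprioritization. Explicitly
  ranked interventions precede unranked ones; unranked keep catalog order;
  ties break alphabetically, so runs are reproducible.

Both rules conserve hours (allocations sum to `min(supply, demand)`) and
never allocate beyond an intervention's demand. The per-intervention cap at
the goal and the aggregate cap coincide under proportional allocation; under
priority-fill the per-intervention view is the informative one.

**Q3, what-if.** Scenarios are immutable values; `edit_scenario()` returns
a new validated scenario (drop, set, scale, set-headcount edits), so
variants sit side by side. `compare_scenarios()` reports absolute and
relative deltas (a zero baseline prints "new") and is antisymmetric by
construction; `frontier()` sweeps a headcount grid for one cadre and flags
where full coverage is reached.

## Fixtures and provenance

Four fixtures encode published national program figures: Rwanda's two
regional typologies and national headcounts, and Zanzibar's volunteer
quantification. Where intervention-level inputs were never published —
Rwanda's catalogs, Zanzibar's final package — the fixtures do **not** invent
them. Rwanda's health-promotion workload is a clearly labeled *synthetic
encoding* of the reported per-CHW aggregates: one workload unit per CHW
receiving 1,300 one-hour contacts a year, against a time policy tuned to
632 service hours (15.8 h/week × 40 weeks). The encoding reproduces the
reported load ratio exactly while making no claim about the underlying
catalog; the country fixtures' `known_values` tables carry each figure with
a source note. The Zanzibar fixture ships with an empty catalog for the same
reason. An illustrative (invented) catalog for experimentation:

```{r zanzibar-demo}
fx <- load_fixture("zanzibar")
demo <- scenario(
  "zanzibar-illustrative", fx$scenario$profile, fx$scenario$cadres,
  list(
    intervention("child-health-visit", "chv", "home-visit",
                 target_spec("stock-group", "under-5"),
                 contacts_per_year = 4, minutes_per_contact = 35,
                 coverage_goal = 0.9),
    intervention("caregiver-group-counseling", "chv", "group-session",
                 target_spec("stock-group", "under-5", in_need_fraction = 0.8),
                 contacts_per_year = 12, minutes_per_contact = 60,
                 group_size = 15, coverage_goal = 0.9)))
chws_needed(demo)
frontier(demo, c(600, 900, 1152, 1400), "chv")
```

## The synthetic-scenario generator

Property tests and the `synth` CLI command draw whole packages from
`synthesize_package()`. Its default ranges emulate a national program:
populations of 5×10⁴–5×10⁶, part-time cadres of 10–40 h/week over 46–52
weeks with travel up to 40% and admin up to 20% of time, doses of 1–12
contacts/year at 10–60 minutes, group sizes 5–30, coverage goals 0.5–1.
Generation is seed-deterministic, leaves the caller's RNG stream untouched,
and satisfies every type invariant by construction. An `integerize` switch
produces whole persons, contacts, and minutes with unit in-need fractions so
demand can be cross-checked against literal per-contact enumeration.

What the generator does *not* emulate: correlated demography (group
fractions are drawn independently), catalogs tailored to cadre scopes, or
empirically calibrated dose parameters. Passing tests therefore certify the
engine's arithmetic and invariants on realistic magnitudes — duality of Q1
and Q2, conservation and monotonicity of allocation, serialization
round-trips — not the realism of any particular country package.

## Numerical choices and limitations

* Problem sizes in the test and acceptance batteries (200 duality
  scenarios, 25 brute-force packages on populations of 200–2,000, 50
  serialization round-trips) keep the whole suite in the seconds range on a
  single core while exercising every branch of the allocation and rounding
  logic.
* Round-trips are asserted to 10⁻⁹ relative tolerance; YAML serialization
  writes 15 significant digits.
* Report files use fixed formatting (6 significant digits for fractions,
  plain integers, stable row order), so repeated runs are byte-identical
  and diffable.
* Degenerate inputs are defined, not accidental: zero demand needs zero
  CHWs; a cadre with demand but zero service time is an explicit
  infeasibility error; an empty catalog validates with a warning.
* The published aggregates the fixtures encode (1,300 vs 632 hours; 169,
  158, 720 persons per CHW; 58,567 CHWs) are reproduced by computation, but
  the full country analyses (e.g. ">95%" coverage for the established
  Rwandan cadres, Zanzibar's 90%-coverage package) are not reproducible
  anywhere, because their intervention-level inputs were never published.
  The engine's behavior on such full catalogs is covered by the synthetic
  property batteries instead.
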