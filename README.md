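# chwplan

Coverage-and-capacity planning for community health worker (CHW) programs.

Ministries of health that field CHW cadres face a recurring arithmetic
problem: the time a package of community services *demands* rarely matches
the time the workforce can *supply*. `chwplan` makes that time-use
accounting explicit and scriptable. From declarative descriptions of a
population, up to six CHW cadres with their time policies, and an
intervention catalog, it answers three planning questions:

1. **Staffing (Q1)** — how many CHWs does each cadre need to deliver every
   intervention at its coverage goal?
2. **Coverage (Q2)** — given fixed headcounts, what share of the assigned
   workload (and of each intervention's goal) is actually achievable?
3. **What-if (Q3)** — how do edits (dropping or rescaling interventions,
   changing headcounts) shift the coverage–capacity balance?

## The model

For an intervention *i* assigned to cadre *c*, annual service time demanded
is

```
D_i = N_i × g_i × f_i × m_i / 60        (hours/year)
N_i = P × (fraction or rate) × in_need × (1 − facility_share)
```

where `P` is total population, `N_i` the community-served target population
(a stock group sized by a fraction, or an annual event stream sized by a
per-person-year rate), `g_i` the coverage goal, `f_i` contacts per target
individual per year, and `m_i` minutes per contact (group sessions divide
contacts by the group size). Supply per CHW is

```
S = (h × w − training − campaigns) × (1 − travel_share − admin_share)
```

with `h` hours/week and `w` weeks/year. Then, per cadre,

* CHWs needed: `ceil(Σ D_i / S)`;
* achievable workload share: `min(1, headcount × S / Σ D_i)`, with
  under-capacity hours rationed across interventions either
  proportionally or by priority (deprioritization).

## Worked example

The package ships fixtures encoding the published figures of two national
program analyses (Rwanda's three-cadre program and Zanzibar's community
health volunteer quantification). The Rwanda "Rural Eastern" typology:

```r
library(chwplan)
fx <- load_fixture("rwanda-eastern")
population_per_chw(fx)
#> [1] 169
summary(expected_coverage(fx$scenario))
#> Scenario 'rwanda-eastern' (proportional allocation)
#>   asm: 3,794 CHWs, 0 h demand vs 2397808 h supply -> 100.0% of workload achievable
#>   binome: 7,799 CHWs, 0 h demand vs 4928968 h supply -> 100.0% of workload achievable
#>   hp-chw: 3,837 CHWs, 4988100 h demand vs 2424984 h supply -> 48.6% of workload achievable
```

Each CHW serves about 169 persons (2,600,814 people over 15,430 CHWs across
the three cadres). The health-promotion cadre is overloaded: its assigned
workload needs 1,300 hours per CHW per year against 632 available, so under
proportional rationing only 48.6% — under half — of the prescribed activity
is materially achievable. The `asm` and `binôme` rows carry headcounts only
(their catalogs were never published), so they show zero modeled demand
here.

A command-line interface wraps the same functions
(`system.file("cli", "chwplan", package = "chwplan")`):

```sh
chwplan coverage rwanda-eastern --out out/        # Q2 tables as CSV
chwplan needed my-scenario.yaml                   # Q1
chwplan compare base.yaml revised.yaml            # Q3 delta tables
chwplan frontier zanzibar --cadre chv --grid 1800,2000,2200,2400
chwplan synth --seed 7 --cadres 2 --interventions 10
```

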