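# wheatgdt

Organ-level, discrete-time simulator of carbon and nitrogen budgets in a
wheat plant with an **explicit growth–defense trade-off**.

Crop growth models are good at light interception, assimilation and biomass
allocation, but they usually hide the cost of defending the plant inside a
generic maintenance term. `wheatgdt` is for modellers and quantitative plant
scientists who want to *see* that cost: every day, each organ splits the
resources it receives hierarchically into **maintenance → defense → growth**,
defense competes with growth as an explicit sink, and single or combined
abiotic–biotic stress scenarios can be compared for non-additive growth
effects.

## The model

The plant is resolved into six functional organs — roots, senescent leaf,
mature leaf, growing leaf, emerging leaf, grain — connected only through a
common labile pool of carbon and nitrogen. Each daily update runs three
phases:

* **Phase A (time *t*)** — sources and signals.
  Leaf CO2 assimilation follows the Farquhar–von Caemmerer–Berry model,

  $$A_n = \min(A_c, A_j, A_p) - R_d,\qquad
    A_c = V_{cmax}\frac{C_i-\Gamma^*}{C_i + K_c(1+O/K_o)},\qquad
    A_j = J\,\frac{C_i-\Gamma^*}{4C_i+8\Gamma^*},$$

  coupled to Ball–Woodrow–Berry stomatal conductance
  $g_s = g_0 + g_1 A_n h_s / c_s$ and solved for $C_i$ by bisection; all
  kinetic parameters are Arrhenius-scaled from 25 °C. Root nitrate uptake
  combines the high-affinity (Michaelis–Menten) and low-affinity (linear)
  transport systems, regulated by root carbon status. Each stressed organ
  emits a local signal $S_0 \in [0,1]$; co-occurring abiotic and biotic
  signals combine through an interaction response surface
  $\min(s_a + s_b + \gamma\,s_a s_b,\,1)$ (or additive / dominance rules).
  A dynamic defense coefficient $D \in [0,1]$ tracks a Hill dose–response of
  $S_0$ with asymmetric first-order induction/relaxation (hysteresis,
  priming).

* **Phase B (*t + δ*)** — new assimilate, absorbed N and remobilized
  senescent-leaf reserves enter the common pool; the integration unit
  aggregates organ signals into a plant status and allocation directives
  (stage-dependent priorities, stress-boosted demand, downregulation of
  source activities).

* **Phase C (*t + 1*)** — pool C and N are shared among organs
  (demand × priority, capped proportional under scarcity), then partitioned
  within each organ: maintenance first — including the defense-augmented
  maintenance respiration
  $R_{maintenance} = R_{basal} + D \times C_{defense}$ — then defense
  synthesis (an explicit sink $\propto D \times$ organ mass, costed at 2–3 g
  glucose per g compound), then structural growth under strict C:N
  stoichiometry (leaf tissue C:N 10–15, proteins 3.5). Unused resources
  return to the pool; every gram is accounted for and audited to 1e-9.

## Worked example

```r
library(wheatgdt)

cfg  <- default_config()          # 150-day season, anthesis at day 80
traj <- run_simulation(cfg)
traj
#> <wgdt_trajectory> 150 days; final biomass 66.141 g (initial 0.950 g); pool C 3.193 g, N 0.1439 g
#>   mass-balance: max residual C 1.34e-14, N 2.73e-14 (0 day(s) flagged)
```

The default plant assimilates 56 g C over the season and converts it into
66 g of structure (grain-dominated after anthesis), with daily carbon and
nitrogen ledgers closing to machine precision.

Comparing a mid-season heat wave, a foliar pathogen, and their combination:

```r
res <- run_scenario_set(default_scenario_set(cfg))
compare_scenarios(res)
#>    variant final_biomass delta_vs_control relative_loss gross_assim_c respiration_c
#> 1  control         66.14            0.000       0.00000         56.36         24.58
#> 2 stress_a         61.15            4.994       0.07550         53.73         24.47
#> 3 stress_b         63.77            2.375       0.03591         53.71         24.25
#> 4 combined         57.09            9.055       0.13690         51.08         23.74

non_additivity_index(res)$nai
#> [1] 0.0255   # > 0: the combination hurts more than the sum of its parts
```

The heat wave costs 7.6 % of final biomass, the pathogen 3.6 %, and the
combination 13.7 % — 2.6 points more than additive (a synergistic
non-additivity index of 0.0255), because the interaction surface amplifies
the combined stress signal where the two events overlap.

A shell front end wraps the same functions:

```sh
wheatgdt run --config scenario.yaml --seed 42 --out runs/
wheatgdt scenarios --out runs/   # control / single / combined comparison
wheatgdt audit --out runs/       # re-check mass balance on written output
wheatgdt defaults                # dump the embedded default config as YAML
```

## Scope

Single plant, daily step, organ scale. No 3D architecture or canopy light
competition, no organ mortality or mechanistic senescence, no soil water or
soil N dynamics (soil nitrate is an exogenous driver), no explicit hormone
state variables — see the methods vignette (`vignettes/methods.Rmd`) for the
model description, parameter rationale and known limitations.
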