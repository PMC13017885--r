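---
title: "Methods: an organ-level wheat simulator with explicit growth-defense trade-offs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an organ-level wheat simulator with explicit growth-defense trade-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatgdt)
```

## What the model is

`wheatgdt` simulates a single wheat plant as six functional organ
compartments (roots, senescent leaf, mature leaf, growing leaf, emerging
leaf, grain) exchanging carbon and nitrogen exclusively through a common
labile pool, at a daily time step. It sits between classical compartmental
crop models and architecturally explicit plant models: organs are resolved
individually, but there is no 3D geometry, no canopy and no light
competition.

The distinguishing feature is that the cost of defending the plant is
explicit rather than buried in a maintenance coefficient. Each organ carries
two stress-related state variables:

* a local stress signal $S_0 \in [0,1]$, set directly by the stress
  intensities acting on the organ that day (co-occurring abiotic and biotic
  intensities combine through a configurable rule, see below);
* a defense coefficient $D \in [0,1]$, which relaxes toward a Hill
  dose-response of $S_0$ with asymmetric first-order kinetics.

$D$ acts in two places. It augments maintenance respiration,
$R_{maintenance} = R_{basal} + D \cdot C_{defense} \cdot m$, and it creates
an explicit defense sink with demand proportional to $D \cdot m$ (organ mass
$m$), costed in glucose equivalents for carbon and through the protein
fraction for nitrogen. Defense therefore competes with growth for the same
delivered resources, which is the trade-off the package exists to expose.

### The daily cycle

Each day runs three strictly ordered phases within one update; the
intermediate instant orders information flow and carries no real duration,
because transport times inside an herbaceous plant are negligible at a daily
resolution.

1. **Sources and signals.** Mature and growing leaves fix carbon
   (Farquhar-von Caemmerer-Berry biochemistry coupled to Ball-Woodrow-Berry
   conductance, solved for $C_i$; parameters Arrhenius-scaled from 25 °C);
   roots take up nitrate (high-affinity Michaelis-Menten plus low-affinity
   linear transport, regulated by root carbon status). Source activity is
   scaled by $1 - \sigma_{max} S_0$ of the source organ, the stress-driven
   source decline. Stress signals and defense coefficients update.
2. **Pooling and integration.** New assimilate and absorbed N enter the
   pool; leaf dark respiration is paid (from the pool first, then the
   leaf's own labile store); the senescent cohort remobilizes a fraction of
   its stores, accelerated by whole-plant stress; organ signals are
   aggregated into a mass-weighted plant status, from which allocation
   directives are derived.
3. **Allocation and partition.** Pool C and N are shared among organs in a
   single pass (full demand when the pool suffices, otherwise capped
   proportional to priority x demand). Within each organ the hierarchy is
   strict: maintenance first (shortfalls draw on the organ's labile store;
   if that fails too, the deficit is logged and defense and growth get
   nothing that day), then defense synthesis with carbon share
   $\varphi = D$ of the post-maintenance delivery, then structural growth
   limited by the stricter of the C and N requirements. Unused resources
   return to the pool and persist there indefinitely.

Every flux is recorded, and `audit_mass_balance()` re-derives the closure
identities $\Delta C = A_{gross} - R_{total}$ and $\Delta N = U_N$ for every
day; the package's own test suite requires residuals below $10^{-9}$
relative on every run it performs (they are at machine precision in
practice).

## Parameters that matter

All parameters live in one nested configuration (`default_config()`,
override via YAML with `parse_config()`). The consequential ones:

| Block | Parameter | Default | Units | Why |
|---|---|---|---|---|
| gas_exchange | `vcmax25`, `jmax25` | 90, 170 | µmol m⁻² s⁻¹ | typical well-fertilized wheat flag-leaf capacities |
| gas_exchange | `kc25`, `ko25`, `gamma_star25`, Ea set | 404.9, 278.4, 42.75 | µmol mol⁻¹ / mmol mol⁻¹ | standard tobacco-derived C3 kinetics at 25 °C |
| gas_exchange | `g0`, `g1` | 0.01, 9 | mol m⁻² s⁻¹, – | conventional BWB fit for C3 cereals |
| uptake | `vmax_hats`, `km_hats`, `k_lats` | 0.015, 0.1, 0.002 | g N g⁻¹ root d⁻¹, mol m⁻³ | sized so seasonal N uptake roughly matches the N bound in the structure the carbon budget can build |
| respiration | `m_base` (leaf) | 0.012 | g C g⁻¹ DM d⁻¹ | maintenance ~1-2% of tissue C per day at 25 °C |
| respiration | `growth_yield` | 0.75 | g DM per g C-substrate basis | classical growth conversion efficiency |
| respiration | `c_defense` | 0.012 | g C g⁻¹ DM d⁻¹ at D = 1 | see calibration below |
| defense | `s50`, `hill_h` | 0.4, 2 | – | sigmoidal activation centred below full stress, saturating at `d_max` = 1 |
| defense | `k_induction`, `k_relaxation` | 0.5, 0.2 | d⁻¹ | induction in ~2-4 days, relaxation over ~1-2 weeks; the asymmetry produces hysteresis and priming |
| defense | `s_def_rate` | 0.012 | g compound g⁻¹ DM d⁻¹ at D = 1 | see calibration below |
| stoichiometry | `tissue_cn` (leaf) | 12.5 | g C / g N | middle of the physiological 10-15 leaf range |
| stoichiometry | `protein_cn` | 3.5 | g C / g N | protein elemental composition |
| stoichiometry | `phenolic_glucose_cost` | 2.5 | g glucose / g compound | middle of the 2-3 range for phenolic synthesis |
| allocation | `g_pot`, `sink_beta` | per organ | g g⁻¹ d⁻¹ | potential growth deliberately generous relative to supply so realized growth is source-limited, as in field cereals |
| allocation | `sigma_max`, `beta_stress` | 0.5, 0.5 | – | half of a source can be shut down at full stress; priority boost toward stressed organs |

**Defense-cost calibration.** `c_defense` and `s_def_rate` were fixed once
so that a mature leaf with $D = 1$ throughout a sustained 20-day biotic
challenge spends 10-15% of its gross photosynthate on defense-associated
carbon (defense respiration plus synthesis substrate), the physiological
range for pathogen-challenged tissue; the defaults land mid-band. The split
is half respiratory, half synthesis substrate, since both cost channels are
documented but their ratio is not. `defense_c_fraction()` recomputes the
share on any run, and `scripts/acceptance.R` reproduces the calibration
end-to-end.

**Defense compound stoichiometry.** Defense compounds are a two-class mix:
a phenolic-like fraction costed at `phenolic_glucose_cost` g glucose per g
(glucose at 0.4 g C g⁻¹) and a protein-like fraction
(`defense_protein_fraction` = 0.3) binding nitrogen at the protein C:N of
3.5 (protein at 0.53 g C g⁻¹, i.e. ~15% N). Of the substrate carbon, 0.6 g
per g of compound is retained in the compound itself and the remainder is
respired as synthesis overhead.

## The synthetic environment

`generate_weather()` produces the daily drivers: sinusoidal seasonal
temperature and PAR with seeded Gaussian noise, AR(1) relative humidity
clamped to [0, 1], constant CO2, and constant (or linearly depleting) soil
nitrate. Stress scenarios are trapezoidal events (linear ramp up over
`ramp_days` from `start_day`, plateau through `end_day`, symmetric ramp down
after it), declared per stressor with a class (abiotic events default to all
organs; biotic events must name their targets, as local infections do).
Same-stressor overlaps combine by maximum; the abiotic and biotic class
signals on an organ then combine by the configured rule — additive,
dominance, or the interaction surface
$\min(s_a + s_b + \gamma s_a s_b, 1)$ whose $\gamma$ makes combined-stress
damage synergistic ($\gamma > 0$) or antagonistic ($\gamma < 0$).

What this emulates: realistic seasonal envelopes, day-to-day weather noise,
and controlled stress timing/intensity experiments. What it does not:
weather autocorrelation beyond humidity, diurnal cycles (PAR is a
midday-equivalent scaled by a 12 h daylight window), co-varying drivers
(heat waves do not dry the air), or feedback from the plant to its
environment (pathogen growth does not depend on host state). Passing tests
therefore demonstrate internal consistency and the intended comparative
statics of the mechanism — not predictive skill on field data, which would
require calibration against measured trajectories.

## Numerical choices

* **Gas-exchange solver.** Bisection on $C_i \in (\Gamma^*, C_a]$ to a
  bracket width of 1e-6 µmol mol⁻¹; chosen over fixed-point iteration for
  guaranteed convergence, and cross-checked in the test suite against a
  100,000-point grid scan (agreement required within 0.1 µmol mol⁻¹).
  In darkness or at full downregulation the closed-form dark solution
  ($A_n = -R_d$, $g_s = g_0$) is used. If assimilation is negative over the
  whole bracket, the solver settles at the upper boundary rather than
  failing.
* **BWB clamp.** The raw linear BWB form yields $g_s < g_0$ for negative
  assimilation; `max(A_n, 0)` is the conventional fix. Boundary-layer
  conductance is omitted ($c_s = C_a$, $h_s$ = air humidity).
* **Arrhenius, not peaked.** Parameters scale with the simple Arrhenius
  form; there is no high-temperature decline, so behaviour above ~40 °C
  overestimates capacity. A documented limitation.
* **One-ulp hygiene.** Re-multiplication after a min() can overshoot the
  available amount by one ulp; defense use is clamped to what was delivered
  and returns are floored at zero. These clamps move at most ~1e-17 g and
  are invisible at the 1e-9 audit tolerance, but keep stocks non-negative
  exactly.
* **Degenerate inputs.** Zero-mass organs (the grain before anthesis)
  assimilate, respire and demand nothing; potential grain growth uses
  `max(mass, m_ref)` with a small reference mass (0.1 g) so the grain can
  initiate from zero at anthesis without a seeded mass transfer. Horizon 0
  yields a trajectory containing only the initial record. `theta = 0` in the
  electron-transport quadratic falls back to the rectangular hyperbola.
* **Ties.** The limitation label takes the first minimum in the order
  Rubisco, electron transport, TPU; the label is diagnostic only.

## Design choices where the design was open

* **Phases within one update.** The sub-daily instants are ordering, not
  durations; allocation decided on day $t$ takes effect in the organs at
  $t + 1$, which is how perception-reallocation delays enter.
* **$\varphi = D$.** The fraction of post-maintenance carbon offered to
  defense is the defense coefficient itself. Allocation must shift
  progressively toward defense with stress; reusing the already-dynamic $D$
  avoids inventing a second free response function.
* **Single-pass pool sharing.** Under scarcity organs receive
  $\min(d_i, pool \cdot w_i d_i / \sum w_j d_j)$ — order-independent, and
  any remainder legitimately persists in the pool (no recursive
  redistribution). Organs with zero effective priority (the grain before
  anthesis) receive nothing even when the pool is ample.
* **C and N allocated independently, reconciled within organs.** The
  inter-organ step treats the two elements separately; stoichiometric
  coupling happens at the growth step, where the realized structural C:N
  equals `tissue_cn` exactly and the surplus element is returned.
* **Maintenance shortfall draws the organ store first**, and only then
  flags a deficit; a deficit zeroes defense and growth for that day but
  never kills the organ (mortality is out of scope).
* **Stage switch.** A single configured anthesis day toggles vegetative to
  reproductive priorities; no thermal-time phenology.
* **Pool persistence.** Unused pool resources neither decay nor leak.
* **Categorical defense mode.** `categorical3` snaps the continuous
  dose-response to {0, d_max/2, d_max} by terciles — a calibration
  convenience for low/moderate/high activation data, off by default.

## Test problem sizes

The package's own suite runs its integration checks on the default 150-day
season (about 3 s per run); mass-balance, defense-off equivalence,
stress-monotonicity (sustained intensities 0-1), and the
non-additivity contrast ($\gamma$ 0 vs 1, four variants each) all use that
horizon. Unit tests use 20-60-day horizons. The gas-exchange oracle scans
120 environmental conditions at 1e5 grid points each. Parameter recovery
estimates $(s_{50}, k_{induction})$ by a two-stage 25 x 25 grid search on a
~50-day noisy activation series ($\sigma = 0.02$) and requires both within
10%.

## Known limitations

* **No organ mortality, no mechanistic senescence, no leaf-area decline.**
  Photosynthetic area persists through grain filling, so late-season
  assimilation — and therefore the harvest index — is overestimated
  relative to a field crop. Final biomass should be read as cumulative
  allocation outcome under the stated assumptions, not as a yield
  prediction.
* **Soil is an exogenous driver**: nitrate concentration is prescribed,
  uptake is not debited from it, and water is absent entirely
  (drought can only be represented as a generic abiotic stress signal).
* **No hormone state variables.** The stress layer is a reduced-order proxy
  chain (signal, dose-response, first-order dynamics); cross-talk between
  signaling pathways is collapsed into the pairwise combination rule.
* **Single plant.** No canopy, no competition, no architecture; the leaf
  classes are fixed cohorts without promotion (an emerging leaf never
  becomes a mature leaf).
* **Pure Arrhenius temperature responses** overestimate capacity at
  supra-optimal temperatures.
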