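---
title: "Modelling an ice-covered shelf food web: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an ice-covered shelf food web: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`shelfweb` is an end-to-end box model of an Arctic continental-shelf
ecosystem. It tracks a single currency — nitrogen — through 35 compartments:
four producers (surface and deep phytoplankton, ice algae, macrophytes),
fifteen consumer guilds from zooplankton and benthos (each with a separate
larval pool) to fish, seabirds, pinnipeds, cetaceans and ice-obligate
maritime mammals (polar bears), and sixteen non-living pools (dissolved
nitrate and ammonia in the surface and deep water columns, in sediment
porewater, and locked in snow and sea ice; detritus in the water column,
sediment and ice; corpses). Space is a coarse box geometry: an inshore and
an offshore surface zone (merged into single surface pools for dissolved
material, matching the reporting layout), a deep offshore layer, an active
sediment layer, and the ice/snow cover. All state masses are
mmol N per square metre of the whole domain.

The dynamics are a coupled ODE system assembled in `state_derivative()`.
Every internal transfer enters a donor-to-recipient flow matrix exactly once;
boundary exchanges (ocean inflow/outflow at prescribed concentrations,
atmospheric deposition, river and meltwater input, migratory-fish exchange,
harvesting) are separate import/export channels; spawning and recruitment
transfers between adult and larval pools sit in a side ledger of their own.
The state derivative is computed as column sums minus row sums of these
ledgers, which makes nitrogen conservation under closed boundaries a
structural property rather than a numerical accident — the conservation test
checks round-off, not model logic.

### Process formulations

The governing equations use the standard forms of the
nutrient–phytoplankton–zooplankton and end-to-end modelling literature:

* **Producer DIN uptake.** Michaelis–Menten kinetics in nitrate and ammonia
  with a saturating light response and Q10 temperature scaling. Ammonia is
  preferred: the nitrate term is multiplied by an inhibition factor
  `k_inh / (k_inh + ammonia)`. The F-ratio (nitrate share of total uptake)
  is an emergent diagnostic.
* **Feeding.** Preference-weighted Holling type II: available food is the
  preference-weighted sum of prey masses, total ingestion saturates with a
  half-saturation in food mass, and per-prey fluxes are apportioned in
  proportion to preference times prey mass. Assimilated intake net of
  excretion becomes growth; faeces go to a guild-specific detritus pool.
* **Mortality.** Linear background mortality everywhere, plus quadratic
  closure on the top predators. Maritime mammals additionally carry an
  interference factor that intensifies their density dependence as ice
  habitat shrinks — competition concentrates on less ice.
* **Habitat.** Maritime mammals feed in proportion to area-weighted ice
  cover; cetaceans in proportion to open water; all other guilds are
  indifferent.
* **Light and ice.** Transmission through the partly ice-covered surface is
  `(1 - C) + C (1 - albedo) exp(-k_ice h_ice - k_snow h_snow)`; in-water
  attenuation uses a background coefficient plus a suspended-sediment term,
  and producers see the layer-mean irradiance. When the ice volume grows,
  surface nitrate, ammonia and phytoplankton (seeding next season's ice
  algae) are entrained in proportion to the freezing rate; when it shrinks,
  the ice-bound pools are released back to the surface in proportion to the
  relative volume loss, together with meltwater DIN carried by the melt
  volume. Atmospheric deposition lands on snow over the ice-covered fraction
  and on the water surface elsewhere.
* **Recycling.** First-order mineralisation of detritus to ammonia in each
  zone, nitrification of ammonia to nitrate, detritus sinking
  (surface to deep to sediment), corpse decay, and porewater–water-column
  nutrient exchange; microbial rates carry their own Q10.
* **Migratory fish.** A fixed boundary stock of which a set fraction is
  present inside the domain during a seasonal window; the pool relaxes
  towards that target, with the relaxation flux booked as a boundary
  exchange. The guild matters through its predation and prey roles, not its
  own dynamics.

Two parameter choices deserve emphasis because the design was genuinely
open. First, all biological Q10 factors default to 1.1 (uptake, feeding)
and 1.5 (microbial cycling) with a 0 degC reference — a weak acute
temperature response typical of polar stenotherms. This makes the simulated
ecosystem respond to climate change primarily through the cryosphere (light
and habitat), not through warming per se: with the cryosphere held at
baseline, four decades of warming move secondary production by well under
five percent. Second, all consumers carry a small quadratic
self-limitation. Without it, the tightly coupled Holling-II oscillators
(zooplankton–fish, benthos chains) produce boom–bust extinction cycles;
with it, the system settles to a stable annual cycle, which is a
precondition for the steady-state experimental design.

### What the defaults are, and are not

The shipped parameter set (`default_params()`) was chosen so the baseline
decade sits in an ice-dominated, oligotrophic regime: perennial ice cover,
roughly 20% annual light transmission, nitrate-replete surface water,
recycling and primary production together dominating the live flow
activity, and a food web whose masses span the observed orders of
magnitude. No fitting to any regional
calibration was performed, and absolute steady-state masses are not claimed
to reproduce the packaged reference inventory; the package's quantitative
claims are the *relative* and *structural* results exercised by the test
suite (cascade direction, knock-out attribution, index behaviour).

## Synthetic decadal drivers

`generate_decadal_drivers()` produces monthly climatologies for 39 forcing
variables per decade, emulating a high-emissions trajectory on a polar
shelf:

* temperatures are truncated sinusoids (sea water floored at -1.8 degC)
  shifted by exactly `warming_per_decade` per decade (1 degC by default);
* surface irradiance follows the astronomical daylight cycle at 76 N
  (polar night in midwinter, about 45 E m^-2 d^-1 peak) and does not trend;
* ice cover and thickness follow a winter plateau with raised-cosine summer
  shoulders; the summer minimum cover declines linearly (0.55/0.59 offshore/
  inshore at baseline — a perennially ice-affected state — reaching
  effectively open water, cover below 1e-4, by the fifth decade) and the
  open-water window widens by 20 days per decade;
* boundary nitrate declines by 3% per decade; other boundary
  concentrations, exchanges, deposition, SPM and waves stay climatological.

Trends are linear in decade index and the generator is fully deterministic
by default (optional multiplicative noise exists but is off, so that the
steady-state attractor is well defined). Monthly values are interpolated
linearly between month midpoints inside the integrator, wrapping at the
year boundary; whether a daily-output model steps or interpolates its
monthly forcing is not observable from published output, and interpolation
was chosen for smoothness.

What the generator does *not* emulate: synoptic variability, trends in
circulation or waves, spatial structure beyond the two-zone split, and any
co-variation between drivers beyond their common seasonal phase. Passing
tests therefore demonstrate the mechanics and the qualitative climate
response of the model, not fidelity to any reanalysis product.

## Numerical choices

* **Calendar.** A 360-day year of twelve 30-day months keeps monthly
  drivers and annual ledgers exactly aligned.
* **Integrator.** Fixed-step classical Runge–Kutta (RK4). Default step
  0.25 d for production runs; the test suite and the acceptance script run
  at 0.5–1 d, which changes annual means by far less than the convergence
  tolerances in use. Donor-limited capping at sub-step level scales down
  all outflows of any pool whose specific outflow would exceed `0.8/step`,
  so no pool can be driven negative within a step; the flow ledger is
  accumulated with the same RK4 weights as the state, so ledger closure
  (inflow - outflow = mass change) holds to round-off.
* **Steady state.** The attractor under fixed climatological forcing is a
  repeating annual cycle. `run_to_steady_state()` iterates annual cycles
  until the maximum relative year-on-year change of annual mean masses
  falls below `tol` (default 1e-6; 1e-3 at test scale), with the
  denominator floored at 0.01 mmol N m^-2 so near-empty pools (ice algae
  and the cryosphere DIN pools in late decades, maritime mammals near
  extinction) are judged on absolute change. The refractory sediment pool
  is inert by construction — it neither receives nor loses nitrogen — so it
  keeps its initial value and is excluded from attractor-identity
  comparisons.
* **Warm starts.** Within an experiment, each decade starts from the
  previous decade's steady state; this shortens convergence without
  changing the attractor (verified by the attractor-independence test).

## Flow-network indices

All indices are computed from the annually integrated internal flow matrix
(demographic transfers excluded; boundary channels kept separately):

* nutrition-mode shares: primary production (all flows into producers),
  recycling (detrital pools to living consumers) and consumption (living to
  living consumers), scaled to percentages; living mass is attributed to
  the same modes, with mixed feeders split by their inbound detritivory:
  consumption ratio;
* trophic levels by exact linear solve of the diet-weighted recursion, with
  producers and non-living pools anchored at level 1 (the convention of the
  network-index literature); omnivory as the diet-weighted squared spread
  of food-source trophic levels;
* internal ascendancy and capacity in base-2 (bits) flow units, boundary
  flows excluded from both;
* dominance of indirect effects from `N = (I - G)^-1` with `G` normalised
  by each recipient's total inflow *including* imports, which keeps `G`
  substochastic (inflow rather than outflow normalisation is a choice; the
  alternative is not observably different in the published statistics);
* net primary production as producer DIN uptake minus producer losses to
  non-producer pools (this package's documented sign convention; the
  statistic can be negative when boundary phytoplankton imports subsidise
  producer losses), and secondary production as assimilated intake net of
  excretion summed over consumer guilds.

Every kernel is verified against an independent brute-force oracle
(iterative trophic-level solve, truncated path-series, direct sum
evaluation) on 200 randomly generated six-node ledgers to 1e-9.

## Experiments and causal attribution

The knock-out machinery holds named driver groups (boundary concentrations,
volume exchanges, the cryosphere block, irradiance, temperatures) at
baseline-decade values while the rest follow the scenario. The attenuation
daughter experiment is represented as parameter overrides
(`k_ice = k_snow = albedo = 0`) on top of the ice knock-out, so light
passes as if the ice were transparent while ice-bound nutrient stays
locked. Run summaries are condensed with a principal component analysis of
standardised (zero mean, unit variance) compartment masses across runs —
masses span five orders of magnitude, so correlation scaling is the only
defensible choice — with a deterministic sign convention (largest-magnitude
loading positive) and zero-variance pools dropped.

## Morris screening

`param_space()` flattens every scalar model parameter (around 220) with
±20% bounds; parameters with zero nominal value — the harvest ratios under
a zero-fishing configuration — get zero-width bounds and are held fixed, so
their elementary effects are exactly zero rather than an artefact of
jitter. The design is the classical randomised one-at-a-time trajectory
scheme on a p-level grid with step `delta = p/(2(p-1))` (p = 4 by default),
`r` trajectories, and `r (k+1)` evaluations. Significance uses a two-sided
one-sample t test of the mean elementary effect at alpha 0.05; the
graphical cut-off rule used alongside published screenings is not formally
defined, so this package states its own rule and makes it configurable.

Screening evaluations converge on the *output metric* (F-ratio or net
primary production) rather than the full state: the metric stabilises
within a few annual cycles, while the slowest top-predator pools can drift
below one percent per year for decades without affecting it. Evaluations
chain along each trajectory (adjacent plan points differ in one parameter,
so the previous end state is the natural warm start), and evaluations whose
metric does not stabilise are excluded with a count. Default screening
scale is r = 4; the acceptance script runs r = 2 at a one-day step, which
is sufficient for effect signs and the significant/inert split reported
there.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the model at a reduced,
documented scale chosen once: one-day integration step, steady-state
tolerance 1e-3 (screening 5e-3 on the metric), cold starts capped at
100–130 years and warm-started decades at 40, and Morris screening at
r = 2. These sizes keep the full pipeline — driver generation, five-decade
grids for the full-climate, ice and attenuation experiments, network
indices, and parameter screening — reproducible on a single CPU while
leaving every scientific assertion at its stated tolerance.

## Known limitations

* The surface inshore/offshore split is merged for dissolved pools, so the
  inshore–offshore exchange driver has no dynamical effect; it is retained
  as a driver channel for the knock-out bookkeeping.
* Ice algae nearly vanish in the seasonally ice-free decades (reseeded each
  winter by freeze entrainment but flushed by the total summer melt); the
  package does not attempt to reproduce their partial persistence.
* The microbial loop is a single implicit mineralisation pathway; there is
  no explicit bacterial compartment.
* Guild composition, physiology and preferences are fixed across decades;
  all rates of change are emergent from forcing, not from adaptation or
  species turnover.
* Absolute masses and absolute index values are not calibrated; only
  relative responses and structural properties are tested.
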