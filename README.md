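# shelfweb

A guild-based nitrogen mass-balance food-web model of an ice-covered Arctic
continental shelf, with sea-ice coupling, decadal climate experiments,
ecological network analysis and parameter sensitivity screening.

## The problem

Sea-ice retreat changes an Arctic shelf ecosystem through several channels
at once: more light enters the water column, nutrients locked in snow and
ice are released, and ice-obligate predators lose hunting habitat while
open-water foragers gain it. Because these drivers co-vary under a warming
scenario, their individual contributions cannot be read off a single
simulation. `shelfweb` is built for exactly this question: it couples a
35-compartment nitrogen food web (nutrients, detritus, plankton, benthos,
fish with larval stages, seabirds, pinnipeds, cetaceans, polar bears) to a
cryosphere, runs each decade of a synthetic high-emissions scenario to its
steady annual cycle, and then isolates causes with knock-out experiments in
which chosen driver groups (boundary concentrations, water exchanges, the
ice variables, irradiance, temperatures) are frozen at baseline values.

The model is a coupled ODE system in nitrogen (mmol N m⁻², 360-day year).
Producers take up DIN with Michaelis–Menten kinetics under a saturating
light response, where transmission through the ice pack is

    T = (1 − C) + C·(1 − α)·exp(−k_ice·h_ice − k_snow·h_snow),

consumers feed by preference-weighted Holling type II with Q10 temperature
scaling, top predators close the web with quadratic mortality (plus an
interference term for polar bears as ice habitat shrinks), and freezing /
melting entrain and release nutrients between the water column and the
snow/ice pools. A fixed-step RK4 integrator accumulates the full
donor→recipient flow ledger, from which the package computes nutrition-mode
shares, trophic levels, omnivory, internal ascendancy/capacity, dominance
of indirect effects, the F-ratio, and net primary and secondary production.
A Morris elementary-effects module screens all ~220 model parameters
against those outputs. Everything is driven by a deterministic synthetic
driver generator (monthly climatologies per decade); the printed reference
mass inventory for the region ships as a fixture.

## Worked example

Headline change statistics from the packaged reference inventory:

```r
library(shelfweb)
inv <- load_mass_fixture()
baseline <- setNames(inv$GL_2010s, inv$compartment)
future   <- setNames(inv$GL_2050s, inv$compartment)
ct <- change_table(baseline, future)
ct[ct$guild %in% c("Maritime mammals", "Planktivorous fish"),
   c("guild", "percent_change", "log10_ratio")]
#>                 guild percent_change log10_ratio
#> 3    Maritime mammals      -66.30816  -0.4724752
#> 19 Planktivorous fish      357.27949   0.6601817
snow_ice_nutrient_change(baseline, future)
#> [1] -68.26365
```

Maritime mammals (polar bears) lose two thirds of their mass while
planktivorous fish more than quadruple, and the nutrient mass locked in
snow and ice drops by 68% — the melt-driven redistribution at the heart of
the trophic cascade.

Running the model itself — one decade to its steady annual cycle, then the
network summary:

```r
p   <- default_params()
cfg <- scenario_config()          # 5 decades, 1 degC/decade, ice retreat
d0  <- generate_decadal_drivers(cfg, 0)
y0  <- run_to_steady_state(reference_state("GL_2010s"), d0, p,
                           tol = 1e-3, max_years = 100, step = 1)
y0
#> <steady_state_result> 74 year(s), converged (metric 0.00099)
ix <- summary_indices(y0$ledger, params = p)
round(ix$shares_flow, 1)
#> primary_production          recycling        consumption
#>               43.9               33.9               22.2
round(c(f_ratio = ix$f_ratio,
        secondary_production = ix$secondary_production), 2)
#>              f_ratio secondary_production
#>                 0.68               613.51
```

The knock-out grid (full climate vs. frozen cryosphere vs. transparent
ice) is one call:

```r
g <- run_experiment_grid(cfg, p,
                         experiments = list("full_climate", "ice",
                                            "attenuation"),
                         state0 = y0$state_end,
                         tol = 1e-3, max_years = 40, step = 1)
```

Under full climate forcing, secondary production rises monotonically
(+55% by the final decade) while the ice knock-out pins it within 0.4% of
baseline — the cascade is carried by the cryosphere, not by warming — and
the attenuation variant (light passes, nutrients stay locked) restores a
+63% increase, showing the cascade is light- rather than nutrient-limited.

## Package layout

- `R/drivers.R` — synthetic decadal driver generator, knock-out specs,
  driver file round-trip
- `R/compartments.R`, `R/params.R` — guild topology and the full parameter
  set (YAML round-trip, flatten/rebuild for screening)
- `R/process.R`, `R/derivative.R`, `R/integrate.R` — process kernels, the
  mass-balance derivative with its flow ledger, RK4 integration and
  steady-state iteration
- `R/indices.R` — flow-network indices and production metrics
- `R/experiments.R`, `R/report.R` — experiment grid, change tables, PCA,
  report rendering
- `R/morris.R` — Morris design, elementary effects, full-model screening
- `vignettes/shelfweb-methods.Rmd` — the model, its assumptions, numerical
  choices and limitations
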