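#' Model compartment inventory
#'
#' The model resolves 35 nitrogen pools: 19 living guilds (producers,
#' zooplankton, benthos, fish with separate larval pools, top predators) and
#' 16 non-living pools (dissolved nutrients in the water column, porewater,
#' snow and ice; detritus in the water column, sediment and ice; corpses).
#' All state masses are mmol N per square metre of the whole model domain.
#'
#' @return Character vector of the 35 internal compartment names, in canonical
#'   order.
#' @export
#' @examples
#' length(compartment_names())
compartment_names <- function() {
  c(
    # living guilds
    "surface_phyt", "deep_phyt", "ice_algae", "macrophytes",
    "omni_zooplankton", "carn_zooplankton",
    "planktivorous_fish", "planktivorous_fish_larvae",
    "demersal_fish", "demersal_fish_larvae",
    "migratory_fish",
    "benthos_sd", "benthos_sd_larvae",
    "benthos_cs", "benthos_cs_larvae",
    "birds", "pinnipeds", "cetaceans", "maritime_mammals",
    # non-living pools
    "corpses",
    "surface_detritus", "deep_detritus", "ice_detritus",
    "sediment_labile", "sediment_refractory",
    "surface_nitrate", "surface_ammonia",
    "deep_nitrate", "deep_ammonia",
    "snow_nitrate", "snow_ammonia",
    "ice_nitrate", "ice_ammonia",
    "porewater_nitrate", "porewater_ammonia"
  )
}

#' @rdname compartment_names
#' @details `producer_names()`, `living_names()`, `detrital_names()` and
#'   `top_predator_names()` return the guild classes used by the network
#'   indices: producers anchor trophic level 1, detrital pools (detritus and
#'   corpses) define recycling flows, and the four top-predator guilds enter
#'   the mass-weighted mean trophic level.
#' @export
producer_names <- function() {
  c("surface_phyt", "deep_phyt", "ice_algae", "macrophytes")
}

#' @rdname compartment_names
#' @export
living_names <- function() {
  compartment_names()[1:19]
}

#' @rdname compartment_names
#' @export
detrital_names <- function() {
  c("corpses", "surface_detritus", "deep_detritus", "ice_detritus",
    "sediment_labile", "sediment_refractory")
}

#' @rdname compartment_names
#' @export
nutrient_names <- function() {
  c("surface_nitrate", "surface_ammonia", "deep_nitrate", "deep_ammonia",
    "snow_nitrate", "snow_ammonia", "ice_nitrate", "ice_ammonia",
    "porewater_nitrate", "porewater_ammonia")
}

#' @rdname compartment_names
#' @export
top_predator_names <- function() {
  c("maritime_mammals", "pinnipeds", "cetaceans", "birds")
}

nitrate_pool_names <- function() {
  c("surface_nitrate", "deep_nitrate", "ice_nitrate", "porewater_nitrate",
    "snow_nitrate")
}

ammonia_pool_names <- function() {
  c("surface_ammonia", "deep_ammonia", "ice_ammonia", "porewater_ammonia",
    "snow_ammonia")
}

#' Display labels for reporting
#'
#' Maps internal compartment names to the labels used in the shipped reference
#' mass inventory and in rendered reports. The labile sediment pool is
#' reported together with the refractory pool under the combined label, so
#' `report_label("sediment_labile")` returns the combined row name.
#'
#' @param name internal compartment name(s); default all.
#' @return Named character vector of display labels.
#' @export
report_label <- function(name = compartment_names()) {
  lab <- c(
    surface_phyt = "Surface layer phytoplankton",
    deep_phyt = "Deep layer phytoplankton",
    ice_algae = "Ice algae",
    macrophytes = "Macrophyte nitrogen",
    omni_zooplankton = "Omnivorous zooplankton",
    carn_zooplankton = "Carnivorous zooplankton",
    planktivorous_fish = "Planktivorous fish",
    planktivorous_fish_larvae = "Planktivorous fish larvae",
    demersal_fish = "Demersal fish",
    demersal_fish_larvae = "Demersal fish larvae",
    migratory_fish = "Migratory fish",
    benthos_sd = "Benthos susp/dep feeders",
    benthos_sd_larvae = "Benthos susp/dep feeders larvae",
    benthos_cs = "Benthos carn/scav feeders",
    benthos_cs_larvae = "Benthos carn/scav feeders larvae",
    birds = "Birds",
    pinnipeds = "Pinnipeds",
    cetaceans = "Cetaceans",
    maritime_mammals = "Maritime mammals",
    corpses = "Corpses",
    surface_detritus = "Surface layer detritus",
    deep_detritus = "Deep layer detritus",
    ice_detritus = "Ice detritus",
    sediment_labile = "Sediment labile plus refractory detritus",
    sediment_refractory = "Sediment refractory detritus",
    surface_nitrate = "Surface layer nitrate",
    surface_ammonia = "Surface layer ammonia",
    deep_nitrate = "Deep layer nitrate",
    deep_ammonia = "Deep layer ammonia",
    snow_nitrate = "Snow nitrate",
    snow_ammonia = "Snow ammonia",
    ice_nitrate = "Ice nitrate",
    ice_ammonia = "Ice ammonia",
    porewater_nitrate = "Sediment porewater nitrate",
    porewater_ammonia = "Sediment porewater ammonia"
  )
  lab[name]
}

#' Food-web topology: guild specifications
#'
#' Returns the guild table used to assemble feeding fluxes: for every consumer
#' a prey list with preference weights (summing to 1), the pool receiving its
#' faeces and its dead bodies, the nutrient pool receiving its excretion, the
#' temperature felt (surface or deep), its ice-habitat dependence, and the
#' larval/adult demographic pairing. Producers have no prey. Preferences and
#' diet breadths follow the usual shelf-sea guild structure: benthos guilds
#' have 3-4 food sources (detritus, kelp, phytoplankton, benthos) while top
#' predators draw on 5+ sources from zooplankton to pinnipeds.
#'
#' @return A named list of guild specifications (class `guild_table`). Each
#'   element has fields `prey`, `pref`, `defecate_to`, `mortality_to`,
#'   `excrete_to`, `temp_zone`, `ice_dependence`, `larva_of`.
#' @export
default_guilds <- function() {
  g <- function(prey = character(), pref = numeric(),
                defecate_to = "surface_detritus",
                mortality_to = "corpses",
                excrete_to = "surface_ammonia",
                temp_zone = "surface",
                ice_dependence = "indifferent",
                larva_of = NA_character_) {
    if (length(pref)) pref <- pref / sum(pref)
    list(prey = prey, pref = pref, defecate_to = defecate_to,
         mortality_to = mortality_to, excrete_to = excrete_to,
         temp_zone = temp_zone, ice_dependence = ice_dependence,
         larva_of = larva_of)
  }
  guilds <- list(
    surface_phyt = g(mortality_to = "surface_detritus"),
    deep_phyt = g(mortality_to = "deep_detritus", temp_zone = "deep"),
    ice_algae = g(mortality_to = "ice_detritus"),
    macrophytes = g(mortality_to = "surface_detritus"),
    omni_zooplankton = g(
      prey = c("surface_phyt", "deep_phyt", "ice_algae",
               "surface_detritus", "deep_detritus"),
      pref = c(0.45, 0.10, 0.10, 0.25, 0.10),
      mortality_to = "surface_detritus"),
    carn_zooplankton = g(
      prey = c("omni_zooplankton", "planktivorous_fish_larvae",
               "demersal_fish_larvae", "benthos_sd_larvae",
               "benthos_cs_larvae", "ice_algae"),
      pref = c(0.75, 0.05, 0.05, 0.05, 0.05, 0.05),
      mortality_to = "surface_detritus"),
    planktivorous_fish = g(
      prey = c("omni_zooplankton", "carn_zooplankton",
               "benthos_sd_larvae", "benthos_cs_larvae"),
      pref = c(0.55, 0.30, 0.075, 0.075),
      defecate_to = "deep_detritus"),
    planktivorous_fish_larvae = g(
      prey = c("omni_zooplankton", "surface_phyt"),
      pref = c(0.6, 0.4),
      mortality_to = "surface_detritus",
      larva_of = "planktivorous_fish"),
    demersal_fish = g(
      prey = c("planktivorous_fish", "benthos_cs", "benthos_sd",
               "carn_zooplankton", "corpses", "migratory_fish"),
      pref = c(0.35, 0.15, 0.25, 0.10, 0.05, 0.10),
      defecate_to = "deep_detritus", excrete_to = "deep_ammonia",
      temp_zone = "deep"),
    demersal_fish_larvae = g(
      prey = c("omni_zooplankton", "surface_phyt"),
      pref = c(0.7, 0.3),
      mortality_to = "surface_detritus",
      larva_of = "demersal_fish"),
    migratory_fish = g(
      prey = c("omni_zooplankton", "carn_zooplankton", "benthos_sd",
               "planktivorous_fish_larvae"),
      pref = c(0.45, 0.35, 0.10, 0.10),
      defecate_to = "deep_detritus"),
    benthos_sd = g(
      prey = c("surface_detritus", "deep_detritus", "deep_phyt",
               "macrophytes"),
      pref = c(0.3, 0.3, 0.2, 0.2),
      defecate_to = "sediment_labile", excrete_to = "porewater_ammonia",
      temp_zone = "deep"),
    benthos_sd_larvae = g(
      prey = c("surface_phyt", "surface_detritus"),
      pref = c(0.5, 0.5),
      mortality_to = "surface_detritus",
      larva_of = "benthos_sd"),
    benthos_cs = g(
      prey = c("benthos_sd", "corpses", "sediment_labile"),
      pref = c(0.55, 0.25, 0.20),
      defecate_to = "sediment_labile", excrete_to = "porewater_ammonia",
      temp_zone = "deep"),
    benthos_cs_larvae = g(
      prey = c("omni_zooplankton", "surface_detritus"),
      pref = c(0.4, 0.6),
      mortality_to = "surface_detritus",
      larva_of = "benthos_cs"),
    birds = g(
      prey = c("planktivorous_fish", "carn_zooplankton", "demersal_fish",
               "benthos_cs", "corpses"),
      pref = c(0.5, 0.2, 0.1, 0.1, 0.1)),
    pinnipeds = g(
      prey = c("planktivorous_fish", "demersal_fish", "carn_zooplankton",
               "benthos_cs", "corpses"),
      pref = c(0.5, 0.25, 0.1, 0.1, 0.05)),
    cetaceans = g(
      prey = c("planktivorous_fish", "carn_zooplankton", "migratory_fish",
               "omni_zooplankton", "demersal_fish"),
      pref = c(0.35, 0.3, 0.15, 0.1, 0.1),
      ice_dependence = "requires_open_water"),
    maritime_mammals = g(
      prey = c("pinnipeds", "corpses", "birds"),
      pref = c(0.65, 0.25, 0.10),
      ice_dependence = "requires_ice")
  )
  stopifnot(identical(names(guilds), living_names()))
  class(guilds) <- "guild_table"
  guilds
}
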