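#' Light transmission through sea ice and snow
#'
#' Fraction of surface irradiance reaching the water column under partial ice
#' cover: the open-water fraction transmits fully at the surface, while the
#' ice-covered fraction transmits `(1 - albedo) * exp(-k_ice*h_ice -
#' k_snow*h_snow)`.
#'
#' @param ice_cover fractional ice cover in \[0,1\].
#' @param ice_thickness,snow_thickness m.
#' @param params a `model_params` list (uses `params$light`).
#' @return Transmitted fraction in \[0,1\].
#' @export
#' @examples
#' light_transmission(1, 2, 0, default_params())
light_transmission <- function(ice_cover, ice_thickness, snow_thickness,
                               params) {
  pl <- params$light
  (1 - ice_cover) +
    ice_cover * (1 - pl$albedo) *
      exp(-pl$k_ice * ice_thickness - pl$k_snow * snow_thickness)
}

#' Q10 temperature scaling
#'
#' @param rate_ref reference rate (d^-1).
#' @param temperature degC.
#' @param q10 Q10 factor (>= 1).
#' @param t_ref reference temperature (degC).
#' @return `rate_ref * q10^((temperature - t_ref)/10)`.
#' @export
q10_scale <- function(rate_ref, temperature, q10, t_ref) {
  rate_ref * q10 ^ ((temperature - t_ref) / 10)
}

#' Specific DIN uptake rates for a producer
#'
#' Michaelis-Menten uptake of nitrate and ammonia modulated by a saturating
#' light response and Q10 temperature scaling. Ammonia is the preferred
#' substrate: the nitrate term carries an ammonia-inhibition factor
#' `k_inh / (k_inh + ammonia)`.
#'
#' @param nitrate,ammonia mmol N m^-3 ambient concentrations.
#' @param irradiance light available to the producer, E m^-2 d^-1.
#' @param temperature degC.
#' @param producer one of [producer_names()].
#' @param params a `model_params` list.
#' @return Named vector `c(nitrate = , ammonia = )` of specific uptake rates
#'   (d^-1), both non-negative.
#' @export
din_uptake <- function(nitrate, ammonia, irradiance, temperature,
                       producer, params) {
  pu <- params$uptake
  q <- q10_scale(1, temperature, pu$q10[[producer]], pu$t_ref[[producer]])
  light <- irradiance / (pu$k_light[[producer]] + irradiance)
  inhib <- pu$k_inhibit[[producer]] / (pu$k_inhibit[[producer]] + ammonia)
  c(nitrate = pu$u_nitrate[[producer]] *
      nitrate / (pu$k_nitrate[[producer]] + nitrate) * inhib * light * q,
    ammonia = pu$u_ammonia[[producer]] *
      ammonia / (pu$k_ammonia[[producer]] + ammonia) * light * q)
}

#' Preference-weighted Holling type II feeding fluxes
#'
#' Available food is the preference-weighted sum of prey masses; total
#' ingestion saturates with a half-saturation in food mass and scales with
#' consumer mass and a Q10 temperature factor. Per-prey fluxes are
#' apportioned in proportion to `preference * prey_mass`.
#'
#' @param consumer_mass mmol N m^-2.
#' @param prey_masses numeric vector of prey standing masses.
#' @param preferences preference weights summing to 1 over the prey.
#' @param consumer consumer guild name.
#' @param temperature degC.
#' @param params a `model_params` list.
#' @param habitat multiplier in \[0,1\] scaling ingestion (ice-habitat
#'   accessibility; default 1).
#' @return Numeric vector of per-prey ingestion fluxes (mmol N m^-2 d^-1).
#' @export
preference_weighted_feeding <- function(consumer_mass, prey_masses,
                                        preferences, consumer, temperature,
                                        params, habitat = 1) {
  if (length(prey_masses) != length(preferences)) {
    stop("prey/preference length mismatch for ", consumer)
  }
  pf <- params$feeding
  weighted <- preferences * pmax(0, prey_masses)
  avail <- sum(weighted)
  if (avail <= 0) return(numeric(length(prey_masses)))
  q <- q10_scale(1, temperature, pf$q10[[consumer]], pf$t_ref[[consumer]])
  total <- consumer_mass * pf$u_max[[consumer]] *
    avail / (pf$k_food[[consumer]] + avail) * q * habitat
  total * weighted / avail
}

#' Ice-habitat accessibility multiplier
#'
#' Guilds that require sea ice (maritime mammals) feed in proportion to the
#' area-weighted ice cover; guilds that require open water (cetaceans) in
#' proportion to the open-water fraction; all other guilds are unaffected.
#'
#' @param ice_cover_inshore,ice_cover_offshore fractional covers in \[0,1\].
#' @param guild guild name (looked up in `guilds`).
#' @param params a `model_params` list (zone areas).
#' @param guilds a guild table from [default_guilds()].
#' @return Multiplier in \[0,1\].
#' @export
habitat_accessibility <- function(ice_cover_inshore, ice_cover_offshore,
                                  guild, params, guilds = default_guilds()) {
  dep <- guilds[[guild]]$ice_dependence
  cover <- params$geometry$area_inshore * ice_cover_inshore +
    params$geometry$area_offshore * ice_cover_offshore
  switch(dep,
         requires_ice = cover,
         requires_open_water = 1 - cover,
         indifferent = 1,
         stop("unknown ice dependence: ", dep))
}
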