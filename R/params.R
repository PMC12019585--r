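#' Default model parameters
#'
#' Builds the full parameter set of the nitrogen mass-balance model. All rates
#' are per day, concentrations mmol N m^-3, masses mmol N m^-2 of whole
#' domain, depths and thicknesses in metres, light in E m^-2 d^-1.
#'
#' The defaults place the baseline (2010s-like) steady state in an
#' ice-dominated, oligotrophic regime: primary production strongly
#' light-limited under perennial ice, nitrate-replete surface waters, and a
#' food web whose activity is dominated by recycling. They are a package
#' design choice, documented in the methods vignette; no claim is made that
#' they reproduce any calibrated regional parameter set.
#'
#' @return Nested named list of class `model_params`. Every leaf is numeric,
#'   so the set can be flattened with [flatten_params()] for sensitivity
#'   screening and written to YAML with [write_params()].
#' @export
#' @examples
#' p <- default_params()
#' p$light$k_ice
default_params <- function() {
  prods <- producer_names()
  cons <- setdiff(living_names(), prods)
  nv <- function(vals, who) stats::setNames(vals, who)
  p <- list(
    geometry = list(
      area_inshore = 0.2,
      area_offshore = 0.8,
      depth_surface = 40,      # m, covers the whole domain
      depth_deep = 160,        # m, under the offshore zone only
      sediment_depth = 0.1,    # m of active sediment
      sediment_porosity = 0.5,
      macrophyte_depth = 10    # m, effective depth of the macrophyte belt
    ),
    light = list(
      k_ice = 1.5,             # m^-1 attenuation in sea ice
      k_snow = 10,             # m^-1 attenuation in snow
      albedo = 0.6,            # ice/snow surface reflection
      k_water = 0.06,          # m^-1 background water-column attenuation
      k_spm = 0.04             # m^-1 per g m^-3 suspended particulate matter
    ),
    uptake = list(
      u_nitrate = nv(c(1.1, 0.8, 0.9, 0.18), prods),
      u_ammonia = nv(c(0.9, 0.7, 0.8, 0.15), prods),
      k_nitrate = nv(c(1.0, 1.0, 1.0, 1.0), prods),
      k_ammonia = nv(c(0.5, 0.5, 0.5, 0.5), prods),
      k_inhibit = nv(c(0.6, 0.6, 0.6, 0.6), prods),  # ammonia inhibition of nitrate uptake
      k_light = nv(c(6, 4, 2.5, 6), prods),          # saturation light intensity
      mort = nv(c(0.05, 0.05, 0.05, 0.004), prods),
      mort_dd = nv(c(0, 0, 0, 1e-4), prods),  # macrophyte self-shading
      # weak acute temperature response, typical of polar stenotherms

      q10 = nv(rep(1.1, 4), prods),
      t_ref = nv(rep(0, 4), prods)
    ),
    feeding = list(
      # consumer order: omnivorous/carnivorous zooplankton; planktivorous
      # fish + larvae; demersal fish + larvae; migratory fish; benthos
      # susp/dep + larvae; benthos carn/scav + larvae; birds; pinnipeds;
      # cetaceans; maritime mammals
      u_max = nv(c(0.35, 0.10, 0.050, 0.12, 0.030, 0.12, 0.040,
                   0.040, 0.080, 0.020, 0.080, 0.020, 0.015, 0.012,
                   0.010), cons),
      k_food = nv(c(10, 10, 10, 10, 10, 10, 10, 30, 10, 40, 10, 4, 4, 4, 2),
                  cons),
      assim = nv(c(0.6, 0.7, 0.75, 0.7, 0.75, 0.7, 0.75,
                   0.5, 0.6, 0.6, 0.6, 0.8, 0.8, 0.8, 0.8), cons),
      excr = nv(c(0.40, 0.35, 0.30, 0.35, 0.30, 0.35, 0.30,
                  0.30, 0.40, 0.30, 0.40, 0.50, 0.45, 0.45, 0.45), cons),
      mort_lin = nv(c(0.0050, 0.0040, 0.0020, 0.010, 0.0015, 0.010, 0.0010,
                      0.0020, 0.010, 0.0020, 0.010, 8e-4, 8e-4, 6e-4, 8e-4),
                    cons),
      # weak quadratic self-limitation on all consumers stabilises the
      # coupled oscillators; strong closure on the top predators
      mort_dd = nv(c(0.002, 0.004, 0.003, 0.01, 0.003, 0.01, 0.005,
                     5e-4, 0.01, 0.001, 0.01, 0.1, 0.08, 0.05, 1.0), cons),
      q10 = nv(rep(1.1, length(cons)), cons),
      t_ref = nv(rep(0, length(cons)), cons),
      interference = 2.0       # maritime-mammal competition as habitat shrinks
    ),
    cycling = list(
      miner_surface = 0.010,   # detritus -> ammonia
      miner_deep = 0.0050,
      miner_sediment = 0.0020,
      miner_ice = 0.0020,
      corpse_decay = 0.020,    # corpses -> deep detritus
      nitrif_surface = 0.050,  # ammonia -> nitrate
      nitrif_deep = 0.050,
      nitrif_porewater = 0.10,
      sink_surface_det = 0.050, # surface -> deep detritus
      sink_deep_det = 0.020,    # deep detritus -> sediment labile
      sink_phyt = 0.010,        # surface -> deep phytoplankton
      sediment_exchange = 0.05, # m d^-1 porewater <-> deep water
      q10 = 1.5,
      t_ref = 0
    ),
    ice = list(
      entrain_eff = 0.5,       # fraction of frozen-in water-column DIN retained
      melt_release = 1.0,      # multiplier on relative ice-volume loss
      min_ice_volume = 0.005,  # m, floor for brine concentration scaling
      brine_fraction = 0.2,
      algae_flush = 0.5        # share of melt-driven ice-algae loss
    ),
    migration = list(
      boundary_stock = 0.6,    # mmol N m^-2 of migratory fish outside the domain
      presence_fraction = 0.35,# share of the stock entering in season
      entry_day = 150,
      exit_day = 270,
      relax_rate = 0.08        # d^-1 approach to the seasonal target
    ),
    demography = list(
      spawn_start = 60, spawn_end = 150, spawn_rate = 0.004,
      recruit_start = 240, recruit_end = 300, recruit_rate = 0.03
    ),
    wave = list(
      macrophyte_disturbance = 0.004  # d^-1 per m significant wave height
    ),
    harvest = nv(rep(0, length(living_names())), living_names())
  )
  class(p) <- c("model_params", "list")
  p
}

#' Flatten and rebuild parameter sets
#'
#' `flatten_params()` turns the nested parameter list into a named numeric
#' vector (one entry per scalar parameter); `unflatten_params()` rebuilds the
#' nested structure from such a vector. Used by the Morris screening, which
#' perturbs one scalar at a time.
#'
#' @param params a `model_params` list.
#' @param x named numeric vector as produced by `flatten_params`.
#' @param skeleton a `model_params` list giving the structure to rebuild into.
#' @return `flatten_params`: named numeric vector. `unflatten_params`: a
#'   `model_params` list.
#' @export
flatten_params <- function(params) {
  unlist(unclass(params))
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(x, skeleton = default_params()) {
  sk <- unclass(skeleton)
  ref <- unlist(sk)
  stopifnot(length(x) == length(ref))
  if (!is.null(names(x))) {
    stopifnot(identical(names(x), names(ref)))
  }
  out <- utils::relist(unname(x), skeleton = sk)
  # relist drops the names of atomic leaves; restore them from the skeleton
  restore <- function(tpl, val) {
    if (is.list(tpl)) {
      stats::setNames(Map(restore, tpl, val), names(tpl))
    } else {
      stats::setNames(as.numeric(val), names(tpl))
    }
  }
  out <- restore(sk, out)
  class(out) <- c("model_params", "list")
  out
}

#' Parameter family tags for sensitivity reporting
#'
#' Assigns each flattened parameter to a broad family: biological event
#' drivers (migration and reproductive dates), fitted ecology (uptake,
#' feeding and mortality parameters), fixed ecology (Q10 factors and
#' reference temperatures), harvest ratios, and physical configuration
#' (geometry and optics).
#'
#' @param names character vector of flattened parameter names.
#' @return Character vector of family tags.
#' @export
param_family <- function(names) {
  fam <- rep("fitted_ecology", length(names))
  fam[grepl("^(geometry|light)\\.", names)] <- "physical_configuration"
  fam[grepl("^harvest\\.", names)] <- "harvest_ratio"
  fam[grepl("\\.(q10|t_ref)", names)] <- "fixed_ecology"
  fam[grepl("^(demography|migration)\\.", names)] <- "biological_event_driver"
  fam[grepl("^migration\\.(boundary_stock|presence_fraction|relax_rate)",
            names)] <- "fitted_ecology"
  fam
}

#' Validate a parameter set
#'
#' Checks structural identity with the default skeleton and the physical
#' invariants: fractions in \[0,1\], rates and half-saturations non-negative,
#' Q10 factors at least 1.
#'
#' @param params a `model_params` list.
#' @return The validated parameter list, invisibly. Errors describe the
#'   offending entries.
#' @export
validate_params <- function(params) {
  x <- flatten_params(params)
  ref <- flatten_params(default_params())
  if (!identical(names(x), names(ref))) {
    extra <- setdiff(names(x), names(ref))
    miss <- setdiff(names(ref), names(x))
    stop("parameter set does not match the model schema; ",
         if (length(extra)) paste0("unknown: ", paste(extra, collapse = ", "), "; "),
         if (length(miss)) paste0("missing: ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(x))) {
    stop("non-finite parameter values: ",
         paste(names(x)[!is.finite(x)], collapse = ", "))
  }
  frac <- grepl("\\.(assim|excr|albedo|entrain_eff|brine_fraction|algae_flush|presence_fraction|sediment_porosity|area_inshore|area_offshore)",
                names(x)) | grepl("^harvest\\.", names(x))
  bad <- frac & (x < 0 | x > 1)
  if (any(bad)) {
    stop("fraction parameters outside [0,1]: ",
         paste(names(x)[bad], collapse = ", "))
  }
  q10 <- grepl("\\.q10", names(x))
  if (any(x[q10] < 1)) {
    stop("Q10 factors below 1: ", paste(names(x)[q10 & x < 1], collapse = ", "))
  }
  nonneg <- !grepl("t_ref", names(x))
  if (any(x[nonneg] < 0)) {
    stop("negative rate/size parameters: ",
         paste(names(x)[nonneg & x < 0], collapse = ", "))
  }
  invisible(params)
}

#' Read and write parameter configurations
#'
#' Parameter sets are persisted as YAML mirroring the nested structure of
#' [default_params()]. On read the file is validated against the model schema.
#'
#' @param params a `model_params` list.
#' @param path file path.
#' @return `write_params`: `path` invisibly. `read_params`: a validated
#'   `model_params` list.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  sk <- unclass(default_params())
  coerce <- function(tpl, val, where) {
    if (is.list(tpl)) {
      if (!is.list(val) || !setequal(names(tpl), names(val))) {
        stop("malformed parameter block at '", where, "'")
      }
      stats::setNames(Map(coerce, tpl, val[names(tpl)],
                          paste0(where, ".", names(tpl))), names(tpl))
    } else {
      v <- unlist(val)
      if (length(v) != length(tpl)) {
        stop("wrong length for parameter '", where, "'")
      }
      if (!is.null(names(tpl)) && !is.null(names(v))) v <- v[names(tpl)]
      stats::setNames(as.numeric(v), names(tpl))
    }
  }
  out <- coerce(sk, raw, "params")
  class(out) <- c("model_params", "list")
  validate_params(out)
  out
}
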