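#' Driver variable inventory
#'
#' Names of the monthly forcing variables: water and air temperatures,
#' surface irradiance, sea-ice and snow state per zone, volume exchanges,
#' boundary concentrations, river/meltwater inputs, atmospheric deposition,
#' suspended sediment, waves, and vertical diffusivity. SO, SI and D denote
#' the surface offshore, surface inshore and deep zones.
#'
#' @return Character vector of driver variable names.
#' @export
driver_names <- function() {
  c("SO_temp", "D_temp", "SI_temp", "SO_AirTemp", "SI_AirTemp",
    "Slight",
    "SO_IceFree", "SI_IceFree", "SO_IceCover", "SI_IceCover",
    "SO_IceThickness", "SI_IceThickness",
    "SO_SnowThickness", "SI_SnowThickness",
    "SO_OceanIN", "D_OceanIN", "SI_OceanIN", "SI_OceanOUT", "SO_SI_flow",
    "SO_nitrate", "SO_ammonia", "SO_phyt", "SO_detritus",
    "D_nitrate", "D_ammonia", "D_phyt", "D_detritus",
    "SI_nitrate", "SI_ammonia", "SI_phyt", "SI_detritus",
    "river_volume", "meltwater_DIN",
    "atm_deposition_wet", "atm_deposition_dry",
    "SPM_inshore", "SPM_offshore_upper",
    "wave_height_inshore", "vertical_diffusivity")
}

#' Knock-out experiment definitions
#'
#' Builds the specification for one causal-inference experiment: the named
#' driver groups are held at baseline-decade values while all other drivers
#' follow the climate scenario. The five named knock-outs freeze, in turn,
#' boundary concentrations, water volume exchanges, the cryosphere variables,
#' surface irradiance, and temperatures. `attenuation` freezes the same
#' drivers as `ice` and additionally flags the optical parameter override
#' (ice/snow attenuation and albedo set to 0), so light passes as if ice were
#' absent while ice-bound nutrient stays locked. `full_climate` holds nothing.
#'
#' @param name one of `"full_climate"`, `"boundary"`, `"flows"`, `"ice"`,
#'   `"light"`, `"temperature"`, `"attenuation"`.
#' @param decade decade index the experiment is run for (0-based), recorded
#'   for bookkeeping.
#' @return List of class `experiment_spec` with fields `name`,
#'   `held_variables`, `param_overrides` and `decade`.
#' @export
#' @examples
#' experiment_spec("ice")$held_variables
experiment_spec <- function(name, decade = 0L) {
  held <- switch(
    name,
    full_climate = character(),
    boundary = c("SO_nitrate", "SO_ammonia", "SO_phyt", "SO_detritus",
                 "D_nitrate", "D_ammonia", "D_phyt", "D_detritus",
                 "SI_nitrate", "SI_ammonia", "SI_phyt", "SI_detritus"),
    flows = c("SO_OceanIN", "D_OceanIN", "SI_OceanIN", "SI_OceanOUT",
              "SO_SI_flow"),
    ice = ,
    attenuation = c("SO_IceFree", "SI_IceFree", "SO_IceCover", "SI_IceCover",
                    "SO_IceThickness", "SI_IceThickness",
                    "SO_SnowThickness", "SI_SnowThickness"),
    light = "Slight",
    temperature = c("SO_temp", "D_temp", "SI_temp", "SO_AirTemp",
                    "SI_AirTemp"),
    stop("unknown experiment: ", name)
  )
  overrides <- if (identical(name, "attenuation")) {
    c(light.k_ice = 0, light.k_snow = 0, light.albedo = 0)
  } else {
    stats::setNames(numeric(), character())
  }
  structure(list(name = name, held_variables = held,
                 param_overrides = overrides, decade = as.integer(decade)),
            class = "experiment_spec")
}

#' Scenario configuration for the synthetic driver generator
#'
#' Defines the decadal climate trajectory the generator emulates: a
#' high-emissions polar shelf warming from a perennially ice-covered 2010s
#' baseline to seasonally ice-free conditions in the final decade. Trends are
#' linear in decade index. Defaults: 5 decades, 1 degC warming per decade,
#' summer ice cover declining by 0.1425 per decade (from a 0.57 summer
#' minimum, reaching effectively open water by decade 4), ice thinning by
#' 0.3 m per decade, the open-water season lengthening by 20 days per decade,
#' boundary nitrate declining by 3% per decade, at latitude 76 N.
#'
#' @param baseline_decade index of the baseline decade (0-based).
#' @param n_decades number of decades simulated.
#' @param warming_per_decade degC added to every temperature series per decade.
#' @param ice_season_shortening_per_decade days of ice season lost per decade.
#' @param ice_cover_decline_per_decade summer minimum ice-cover loss per decade.
#' @param thickness_decline_per_decade m of winter ice thickness lost per decade.
#' @param boundary_nitrate_trend fractional decline of boundary nitrate per decade.
#' @param latitude degrees north, used for the astronomical daylight cycle.
#' @param seed integer seed for optional generator noise.
#' @param noise_sd relative standard deviation of multiplicative noise;
#'   0 (default) keeps the generator fully deterministic so steady-state
#'   attractors are well defined.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(baseline_decade = 0L,
                            n_decades = 5L,
                            warming_per_decade = 1.0,
                            ice_season_shortening_per_decade = 20,
                            ice_cover_decline_per_decade = 0.1425,
                            thickness_decline_per_decade = 0.3,
                            boundary_nitrate_trend = 0.03,
                            latitude = 76,
                            seed = 1L,
                            noise_sd = 0) {
  if (n_decades < 1) stop("n_decades must be at least 1")
  if (latitude < 60 || latitude > 90) stop("latitude must lie in [60, 90]")
  if (warming_per_decade < 0 || ice_season_shortening_per_decade < 0 ||
      ice_cover_decline_per_decade < 0 || thickness_decline_per_decade < 0 ||
      boundary_nitrate_trend < 0) {
    stop("trend magnitudes must be non-negative")
  }
  structure(list(baseline_decade = as.integer(baseline_decade),
                 n_decades = as.integer(n_decades),
                 warming_per_decade = warming_per_decade,
                 ice_season_shortening_per_decade = ice_season_shortening_per_decade,
                 ice_cover_decline_per_decade = ice_cover_decline_per_decade,
                 thickness_decline_per_decade = thickness_decline_per_decade,
                 boundary_nitrate_trend = boundary_nitrate_trend,
                 latitude = latitude, seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "scenario_config")
}

# month midpoints of the 360-day model year
month_midday <- function() (seq_len(12) - 0.5) * 30

# smooth 0..1 summer bump: 1 inside the open-season plateau, raised-cosine
# shoulders of fixed width either side
season_shape <- function(day, centre = 210, half_width = 50, shoulder = 60) {
  d <- abs(day - centre)
  d <- pmin(d, 360 - d)  # wrap
  s <- numeric(length(d))
  s[d <= half_width] <- 1
  ramp <- d > half_width & d < half_width + shoulder
  s[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - half_width) / shoulder))
  s
}

# daily astronomical irradiance at latitude (E m^-2 d^-1), 360-day calendar
daily_irradiance <- function(day, latitude, scale = 1.3) {
  decl <- -23.44 * cos(2 * pi * (day + 10) / 360) * pi / 180
  phi <- latitude * pi / 180
  x <- -tan(phi) * tan(decl)
  h0 <- acos(pmin(1, pmax(-1, x)))   # half day length (radians)
  q <- (36 / pi) * (h0 * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(h0))
  pmax(0, q * scale)
}

#' Generate a decadal monthly driver set
#'
#' Produces the 12-month climatological forcing for one decade of the
#' synthetic climate scenario. Seasonal shapes are smooth: temperatures and
#' irradiance are (truncated) sinusoids, ice cover and thickness follow a
#' winter plateau with raised-cosine summer shoulders whose open-water window
#' widens with decade. All temperature series are shifted by exactly
#' `decade * warming_per_decade`; summer ice cover, ice thickness and snow
#' thickness decline linearly; boundary nitrate declines by the configured
#' fraction per decade. Irradiance follows the astronomical daylight cycle at
#' the configured latitude and does not trend. With `noise_sd = 0` (default)
#' the output is fully deterministic given `(config, decade)`.
#'
#' @param config a [scenario_config()].
#' @param decade decade index, `0 <= decade < config$n_decades`.
#' @return A `driver_set`: a 12 x 39 numeric matrix (months x variables) with
#'   a `decade_label` attribute.
#' @export
#' @examples
#' d0 <- generate_decadal_drivers(scenario_config(), 0)
#' range(d0[, "SO_IceCover"])
generate_decadal_drivers <- function(config, decade) {
  if (!inherits(config, "scenario_config")) stop("config must be a scenario_config")
  if (decade < 0 || decade >= config$n_decades) {
    stop("decade index out of range [0, ", config$n_decades - 1, "]")
  }
  d <- as.numeric(decade)
  day <- month_midday()
  vars <- driver_names()
  m <- matrix(0, nrow = 12, ncol = length(vars),
              dimnames = list(month = NULL, variable = vars))

  warm <- d * config$warming_per_decade
  # water temperatures: sinusoid truncated at the freezing point of seawater,
  # then shifted linearly so decade differences are exact
  t_so <- pmax(-1.8, -1.0 + 1.6 * cos(2 * pi * (day - 225) / 360))
  t_si <- pmax(-1.8, -1.2 + 1.8 * cos(2 * pi * (day - 225) / 360))
  t_d <- pmax(-1.8, -0.5 + 0.4 * cos(2 * pi * (day - 255) / 360))
  m[, "SO_temp"] <- t_so + warm
  m[, "SI_temp"] <- t_si + warm
  m[, "D_temp"] <- t_d + warm
  m[, "SO_AirTemp"] <- -14 + 13 * cos(2 * pi * (day - 210) / 360) + warm
  m[, "SI_AirTemp"] <- -16 + 14 * cos(2 * pi * (day - 210) / 360) + warm

  m[, "Slight"] <- daily_irradiance(day, config$latitude)

  # cryosphere: winter plateau, summer trough that deepens and widens
  hw <- 50 + d * config$ice_season_shortening_per_decade / 2
  s <- season_shape(day, centre = 210, half_width = hw)
  winter_cover <- c(SO = 0.97, SI = 0.98) - 0.03 * d
  summer_cover <- c(SO = max(2e-5, 0.55 - d * config$ice_cover_decline_per_decade),
                    SI = max(5e-5, 0.59 - d * config$ice_cover_decline_per_decade))
  winter_thick <- max(0.05, 2.0 - d * config$thickness_decline_per_decade)
  summer_thick <- max(0.01, 1.0 - d * config$thickness_decline_per_decade)
  winter_snow <- max(0, 0.30 - d * 0.05)
  for (z in c("SO", "SI")) {
    cov <- winter_cover[[z]] - (winter_cover[[z]] - summer_cover[[z]]) * s
    thick <- winter_thick - (winter_thick - summer_thick) * s
    m[, paste0(z, "_IceCover")] <- cov
    m[, paste0(z, "_IceFree")] <- 1 - cov
    m[, paste0(z, "_IceThickness")] <- thick
    m[, paste0(z, "_SnowThickness")] <- winter_snow * (1 - s) * (thick > 0)
  }

  # volume exchanges (fraction of zone volume per day), weak seasonality
  circ <- 1 + 0.2 * cos(2 * pi * (day - 30) / 360)
  m[, "SO_OceanIN"] <- 0.020 * circ
  m[, "D_OceanIN"] <- 0.010 * circ
  m[, "SI_OceanIN"] <- 0.015 * circ
  m[, "SI_OceanOUT"] <- 0.015 * circ
  m[, "SO_SI_flow"] <- 0.005 * circ

  # boundary concentrations (mmol N m^-3)
  ntrend <- max(0, 1 - d * config$boundary_nitrate_trend)
  bloom <- season_shape(day, centre = 195, half_width = 30, shoulder = 45)
  m[, "SO_nitrate"] <- (14 - 6 * bloom) * ntrend
  m[, "SI_nitrate"] <- (12 - 5 * bloom) * ntrend
  m[, "D_nitrate"] <- 12 * ntrend
  m[, "SO_ammonia"] <- 0.6 + 0.3 * bloom
  m[, "SI_ammonia"] <- 0.6 + 0.3 * bloom
  m[, "D_ammonia"] <- 0.8
  m[, "SO_phyt"] <- 0.05 + 1.2 * bloom
  m[, "SI_phyt"] <- 0.05 + 1.0 * bloom
  m[, "D_phyt"] <- 0.02 + 0.2 * bloom
  m[, "SO_detritus"] <- 0.3 + 0.3 * bloom
  m[, "SI_detritus"] <- 0.3 + 0.3 * bloom
  m[, "D_detritus"] <- 0.4

  # river/meltwater, deposition, SPM, waves, mixing
  melt_season <- season_shape(day, centre = 210, half_width = 40)
  m[, "river_volume"] <- 0.0015 * melt_season
  m[, "meltwater_DIN"] <- 2.0
  m[, "atm_deposition_wet"] <- 0.0020
  m[, "atm_deposition_dry"] <- 0.0010
  m[, "SPM_inshore"] <- 1.0 + 0.5 * melt_season
  m[, "SPM_offshore_upper"] <- 0.4 + 0.2 * melt_season
  m[, "wave_height_inshore"] <- 0.6 + 0.4 * season_shape(day, centre = 300,
                                                         half_width = 60)
  m[, "vertical_diffusivity"] <- 12 - 8 * season_shape(day, centre = 210,
                                                       half_width = 60)

  if (config$noise_sd > 0) {
    old <- .Random.seed__save()
    set.seed((config$seed + 7919L * (as.integer(decade) + 1L)) %% 2147483647L)
    fac <- matrix(exp(stats::rnorm(length(m), 0, config$noise_sd)), nrow = 12)
    m <- m * fac
    .Random.seed__restore(old)
    # clamp fractional channels back into [0, 1]
    frac <- c("SO_IceFree", "SI_IceFree", "SO_IceCover", "SI_IceCover")
    m[, frac] <- pmin(1, pmax(0, m[, frac]))
  }

  structure(m, class = c("driver_set", "matrix", "array"),
            decade_label = sprintf("decade_%d", as.integer(decade)))
}

.Random.seed__save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed__restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Apply a knock-out to a scenario driver set
#'
#' Returns `scenario_drivers` with every held variable of the experiment
#' copied verbatim from `baseline_drivers`, leaving all other series to
#' follow the climate scenario.
#'
#' @param scenario_drivers,baseline_drivers `driver_set` matrices sharing the
#'   full variable inventory.
#' @param experiment an [experiment_spec()].
#' @return A `driver_set`.
#' @export
apply_knockout <- function(scenario_drivers, baseline_drivers, experiment) {
  held <- experiment$held_variables
  unknown <- setdiff(held, colnames(scenario_drivers))
  if (length(unknown)) {
    stop("unknown driver variable(s) in held set: ",
         paste(unknown, collapse = ", "))
  }
  stopifnot(identical(colnames(scenario_drivers), colnames(baseline_drivers)))
  out <- scenario_drivers
  if (length(held)) out[, held] <- baseline_drivers[, held]
  attr(out, "decade_label") <- attr(scenario_drivers, "decade_label")
  out
}

#' Persist and reload driver sets
#'
#' Driver sets are written as long-format CSV with columns
#' `(variable, month, value)` preceded by commented metadata header lines.
#' `read_drivers()` validates that every inventory variable is present with
#' exactly 12 monthly values and that no unknown variables appear.
#'
#' @param driver_set a `driver_set`.
#' @param path file path.
#' @return `write_drivers`: `path`, invisibly. `read_drivers`: a `driver_set`
#'   equal to the one written, to full stored precision.
#' @export
write_drivers <- function(driver_set, path) {
  long <- data.frame(
    variable = rep(colnames(driver_set), each = 12),
    month = rep(seq_len(12), times = ncol(driver_set)),
    value = sprintf("%.17g", as.vector(driver_set))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# shelfweb driver set (long format: variable, month, value)",
    paste0("# decade_label: ", attr(driver_set, "decade_label") %||% "unknown")
  ), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_drivers
#' @export
read_drivers <- function(path) {
  header <- readLines(path, n = 20)
  meta <- grep("^# decade_label: ", header, value = TRUE)
  label <- if (length(meta)) sub("^# decade_label: ", "", meta[[1]]) else "unknown"
  long <- utils::read.csv(path, comment.char = "#",
                          colClasses = c("character", "integer", "numeric"))
  vars <- driver_names()
  unknown <- setdiff(unique(long$variable), vars)
  if (length(unknown)) {
    stop("unknown driver variable(s) in file: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(vars, unique(long$variable))
  if (length(missing)) {
    stop("missing driver variable(s): ", paste(missing, collapse = ", "))
  }
  counts <- table(long$variable)
  bad <- names(counts)[counts != 12]
  if (length(bad)) {
    stop("variables without exactly 12 monthly values: ",
         paste(bad, collapse = ", "))
  }
  m <- matrix(0, 12, length(vars), dimnames = list(month = NULL, variable = vars))
  for (v in vars) {
    rows <- long[long$variable == v, ]
    if (any(sort(rows$month) != seq_len(12))) {
      stop("months for ", v, " are not 1..12")
    }
    m[rows$month, v] <- rows$value
  }
  structure(m, class = c("driver_set", "matrix", "array"), decade_label = label)
}

#' Interpolate monthly drivers to an arbitrary model day
#'
#' Drivers are defined as monthly climatologies on a 360-day year; inside the
#' integrator they are linearly interpolated between month midpoints,
#' wrapping at the year boundary.
#'
#' @param driver_set a `driver_set`.
#' @param t model day (any real number; wrapped into \[0, 360)).
#' @return Named numeric vector of all driver values at day `t`.
#' @export
drivers_at <- function(driver_set, t) {
  day <- t %% 360
  pos <- day / 30 + 0.5          # fractional month index, midpoints at 1..12
  m1 <- floor(pos)
  w <- pos - m1
  i1 <- ((as.integer(m1) - 1L) %% 12L) + 1L
  i2 <- (as.integer(m1) %% 12L) + 1L
  v <- (1 - w) * driver_set[i1, ] + w * driver_set[i2, ]
  names(v) <- colnames(driver_set)
  v
}

#' @export
print.driver_set <- function(x, ...) {
  cat("<driver_set> ", attr(x, "decade_label"), ": 12 months x ",
      ncol(x), " variables\n", sep = "")
  invisible(x)
}
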