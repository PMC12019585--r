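# Assembly of the nitrogen mass-balance derivative. Every internal transfer
# is entered once in a donor -> recipient flow matrix; boundary exchanges go
# into separate import/export channels; demographic (spawning/recruitment)
# transfers live in their own matrix so the food-web flow ledger can exclude
# them. The state derivative is then column sums minus row sums, which makes
# nitrogen conservation with closed boundaries structural rather than
# numerical.
#
# All driver-derived quantities (transmitted light, temperature scalings,
# boundary import fluxes and export rates, ice volume) are precomputed as
# monthly series when the context is built, and linearly interpolated
# between month midpoints inside the derivative; only state-dependent terms
# are evaluated per call.

# Precomputed index tables, aligned parameter vectors and (when drivers are
# supplied) monthly series; rebuild whenever params, guilds or drivers
# change. The integrator builds one per run.
build_context <- function(params, guilds = default_guilds(), drivers = NULL) {
  cn <- compartment_names()
  idx <- stats::setNames(seq_along(cn), cn)
  cons_names <- names(guilds)[vapply(guilds, function(g) length(g$prey) > 0,
                                     logical(1))]
  consumers <- lapply(cons_names, function(nm) {
    g <- guilds[[nm]]
    list(name = nm, i = idx[[nm]],
         prey = unname(idx[g$prey]), pref = g$pref,
         prey_mat = cbind(unname(idx[g$prey]), idx[[nm]]),
         def = idx[[g$defecate_to]], mort = idx[[g$mortality_to]],
         exc = idx[[g$excrete_to]],
         deep = identical(g$temp_zone, "deep"),
         dep = g$ice_dependence,
         u_max = params$feeding$u_max[[nm]],
         k_food = params$feeding$k_food[[nm]],
         assim = params$feeding$assim[[nm]],
         excr = params$feeding$excr[[nm]],
         mort_lin = params$feeding$mort_lin[[nm]],
         mort_dd = params$feeding$mort_dd[[nm]],
         q10 = params$feeding$q10[[nm]],
         t_ref = params$feeding$t_ref[[nm]])
  })
  pairs <- list()
  for (nm in names(guilds)) {
    ad <- guilds[[nm]]$larva_of
    if (!is.na(ad)) pairs[[length(pairs) + 1L]] <- c(adult = idx[[ad]],
                                                     larva = idx[[nm]])
  }
  ctx <- list(idx = idx, n = length(cn), cn = cn,
              dn = list(donor = cn, recipient = cn), consumers = consumers,
              pairs = pairs,
              any_harvest = any(params$harvest > 0),
              harvest = stats::setNames(params$harvest[living_names()],
                                        living_names()),
              rc = NULL)
  if (!is.null(drivers)) ctx$rc <- precompute_run(params, guilds, drivers, ctx)
  ctx
}

# monthly driver-derived series used by the derivative
precompute_run <- function(params, guilds, drivers, ctx) {
  geo <- params$geometry
  aI <- geo$area_inshore; aO <- geo$area_offshore
  v_surf <- geo$depth_surface
  v_deep <- aO * geo$depth_deep
  v_pore <- geo$sediment_depth * geo$sediment_porosity
  D <- drivers

  temp_surf <- aI * D[, "SI_temp"] + aO * D[, "SO_temp"]
  temp_deep <- D[, "D_temp"]
  cover <- aI * D[, "SI_IceCover"] + aO * D[, "SO_IceCover"]
  thick <- aI * D[, "SI_IceThickness"] + aO * D[, "SO_IceThickness"]
  snow <- aI * D[, "SI_SnowThickness"] + aO * D[, "SO_SnowThickness"]
  iv12 <- aI * D[, "SI_IceCover"] * D[, "SI_IceThickness"] +
    aO * D[, "SO_IceCover"] * D[, "SO_IceThickness"]
  sv12 <- aI * D[, "SI_IceCover"] * D[, "SI_SnowThickness"] +
    aO * D[, "SO_IceCover"] * D[, "SO_SnowThickness"]

  trans <- aI * light_transmission(D[, "SI_IceCover"], D[, "SI_IceThickness"],
                                   D[, "SI_SnowThickness"], params) +
    aO * light_transmission(D[, "SO_IceCover"], D[, "SO_IceThickness"],
                            D[, "SO_SnowThickness"], params)
  I0 <- D[, "Slight"]
  spm_w <- aI * D[, "SPM_inshore"] + aO * D[, "SPM_offshore_upper"]
  k_surf <- params$light$k_water + params$light$k_spm * spm_w
  I_surf_top <- I0 * trans
  I_surf <- I_surf_top * (1 - exp(-k_surf * v_surf)) / (k_surf * v_surf)
  I_deep_top <- I_surf_top * exp(-k_surf * v_surf)
  k_deep <- params$light$k_water
  Hd <- geo$depth_deep
  I_deep <- I_deep_top * (1 - exp(-k_deep * Hd)) / (k_deep * Hd)
  I_ice <- I0 * (1 - params$light$albedo) *
    exp(-params$light$k_snow * snow - 0.5 * params$light$k_ice * thick)
  k_in <- params$light$k_water + params$light$k_spm * D[, "SPM_inshore"]
  trans_in <- light_transmission(D[, "SI_IceCover"], D[, "SI_IceThickness"],
                                 D[, "SI_SnowThickness"], params)
  I_mac <- I0 * trans_in * exp(-k_in * geo$macrophyte_depth)

  pu <- params$uptake
  ufac <- function(prod, I, temp) {
    I / (pu$k_light[[prod]] + I) *
      pu$q10[[prod]] ^ ((temp - pu$t_ref[[prod]]) / 10)
  }
  uptake_fac <- cbind(
    surface_phyt = ufac("surface_phyt", I_surf, temp_surf),
    deep_phyt = ufac("deep_phyt", I_deep, temp_deep),
    ice_algae = ufac("ice_algae", I_ice, pmin(temp_surf, 0)) * cover,
    macrophytes = ufac("macrophytes", I_mac, temp_surf))

  feed_fac <- vapply(ctx$consumers, function(cc) {
    temp <- if (cc$deep) temp_deep else temp_surf
    hab <- switch(cc$dep, requires_ice = cover,
                  requires_open_water = 1 - cover, rep(1, 12))
    cc$u_max * cc$q10 ^ ((temp - cc$t_ref) / 10) * hab
  }, numeric(12))
  dd_fac <- vapply(ctx$consumers, function(cc) {
    dd <- cc$mort_dd
    if (dd > 0 && identical(cc$name, "maritime_mammals")) {
      hab <- cover
      dd * (1 + params$feeding$interference * (1 - hab))
    } else rep(dd, 12)
  }, numeric(12))

  cyc <- params$cycling
  q_s <- cyc$q10 ^ ((temp_surf - cyc$t_ref) / 10)
  q_d <- cyc$q10 ^ ((temp_deep - cyc$t_ref) / 10)
  vel_mix12 <- D[, "vertical_diffusivity"] /
    ((geo$depth_surface + geo$depth_deep) / 2)

  # first-order internal transfers: donor, recipient, monthly rate series
  ii <- ctx$idx
  ones <- rep(1, 12)
  lin <- list(
    c("corpses", "deep_detritus"), c("surface_detritus", "surface_ammonia"),
    c("deep_detritus", "deep_ammonia"), c("sediment_labile", "porewater_ammonia"),
    c("ice_detritus", "ice_ammonia"), c("surface_ammonia", "surface_nitrate"),
    c("deep_ammonia", "deep_nitrate"), c("porewater_ammonia", "porewater_nitrate"),
    c("surface_detritus", "deep_detritus"),
    c("surface_detritus", "sediment_labile"),
    c("deep_detritus", "sediment_labile"), c("surface_phyt", "deep_phyt"),
    c("surface_phyt", "surface_detritus"), c("deep_phyt", "deep_detritus"),
    c("ice_algae", "ice_detritus"), c("macrophytes", "surface_detritus"))
  lin_d <- vapply(lin, function(p) ii[[p[1]]], integer(1))
  lin_r <- vapply(lin, function(p) ii[[p[2]]], integer(1))
  wave_mort <- params$wave$macrophyte_disturbance * D[, "wave_height_inshore"]
  lin_rate12 <- cbind(
    cyc$corpse_decay * q_d, cyc$miner_surface * q_s, cyc$miner_deep * q_d,
    cyc$miner_sediment * q_d, cyc$miner_ice * ones, cyc$nitrif_surface * q_s,
    cyc$nitrif_deep * q_d, cyc$nitrif_porewater * q_d,
    cyc$sink_surface_det * aO * ones, cyc$sink_surface_det * aI * ones,
    cyc$sink_deep_det * ones, cyc$sink_phyt * aO * ones,
    pu$mort[["surface_phyt"]] * ones, pu$mort[["deep_phyt"]] * ones,
    pu$mort[["ice_algae"]] * ones, pu$mort[["macrophytes"]] + wave_mort)

  prod_i <- unname(ii[producer_names()])
  nit_pair <- cbind(unname(ii[c("surface_nitrate", "deep_nitrate",
                                "ice_nitrate", "surface_nitrate")]), prod_i)
  amm_pair <- cbind(unname(ii[c("surface_ammonia", "deep_ammonia",
                                "ice_ammonia", "surface_ammonia")]), prod_i)
  prod_mort_pair <- cbind(prod_i, unname(ii[c("surface_detritus",
                                              "deep_detritus", "ice_detritus",
                                              "surface_detritus")]))

  # boundary imports (driver-only) and specific export rates
  n <- ctx$n
  idx <- ctx$idx
  imp12 <- matrix(0, 12, n)
  exr12 <- matrix(0, 12, n)
  vSO <- aO * v_surf; vSI <- aI * v_surf
  imp12[, idx[["surface_nitrate"]]] <-
    D[, "SO_OceanIN"] * vSO * D[, "SO_nitrate"] +
    D[, "SI_OceanIN"] * vSI * D[, "SI_nitrate"] +
    D[, "atm_deposition_wet"] * (1 - cover) +
    0.7 * D[, "river_volume"] * vSI * D[, "meltwater_DIN"]
  imp12[, idx[["surface_ammonia"]]] <-
    D[, "SO_OceanIN"] * vSO * D[, "SO_ammonia"] +
    D[, "SI_OceanIN"] * vSI * D[, "SI_ammonia"] +
    D[, "atm_deposition_dry"] * (1 - cover) +
    0.3 * D[, "river_volume"] * vSI * D[, "meltwater_DIN"]
  imp12[, idx[["surface_phyt"]]] <-
    D[, "SO_OceanIN"] * vSO * D[, "SO_phyt"] +
    D[, "SI_OceanIN"] * vSI * D[, "SI_phyt"]
  imp12[, idx[["surface_detritus"]]] <-
    D[, "SO_OceanIN"] * vSO * D[, "SO_detritus"] +
    D[, "SI_OceanIN"] * vSI * D[, "SI_detritus"]
  imp12[, idx[["snow_nitrate"]]] <- D[, "atm_deposition_wet"] * cover
  imp12[, idx[["snow_ammonia"]]] <- D[, "atm_deposition_dry"] * cover
  ex_d <- D[, "D_OceanIN"] * v_deep
  imp12[, idx[["deep_nitrate"]]] <- ex_d * D[, "D_nitrate"]
  imp12[, idx[["deep_ammonia"]]] <- ex_d * D[, "D_ammonia"]
  imp12[, idx[["deep_phyt"]]] <- ex_d * D[, "D_phyt"]
  imp12[, idx[["deep_detritus"]]] <- ex_d * D[, "D_detritus"]
  ex_out <- (D[, "SO_OceanIN"] * vSO + D[, "SI_OceanIN"] * vSI +
               D[, "SI_OceanOUT"] * vSI) / v_surf
  for (nm in c("surface_nitrate", "surface_ammonia", "surface_phyt",
               "surface_detritus")) {
    exr12[, idx[[nm]]] <- ex_out
  }
  for (nm in c("deep_nitrate", "deep_ammonia", "deep_phyt",
               "deep_detritus")) {
    exr12[, idx[[nm]]] <- ex_d / v_deep
  }

  list(aI = aI, aO = aO, v_surf = v_surf, v_deep = v_deep, v_pore = v_pore,
       cover = cover, iv12 = iv12, sv12 = sv12,
       uptake_fac = uptake_fac, feed_fac = feed_fac, dd_fac = dd_fac,
       vel_mix12 = vel_mix12, lin_d = lin_d, lin_r = lin_r,
       lin_pair = cbind(lin_d, lin_r), lin_rate12 = lin_rate12,
       prod_i = prod_i, nit_pair = nit_pair, amm_pair = amm_pair,
       prod_mort_pair = prod_mort_pair, prod_dd = unname(pu$mort_dd),
       u_n = unname(pu$u_nitrate), u_a = unname(pu$u_ammonia),
       k_n = unname(pu$k_nitrate), k_a = unname(pu$k_ammonia),
       k_i = unname(pu$k_inhibit),
       imp12 = imp12, exr12 = exr12,
       meltwater_DIN = D[, "meltwater_DIN"],
       sediment_exchange = params$cycling$sediment_exchange,
       entrain_eff = params$ice$entrain_eff,
       melt_release = params$ice$melt_release,
       min_ice_volume = params$ice$min_ice_volume,
       brine_fraction = params$ice$brine_fraction,
       algae_flush = params$ice$algae_flush,
       mig = params$migration, dem = params$demography)
}

# interpolation weights on the 360-day year (month midpoints)
month_weights <- function(t) {
  day <- t %% 360
  pos <- day / 30 + 0.5
  m1 <- floor(pos)
  w <- pos - m1
  i1 <- ((as.integer(m1) - 1L) %% 12L) + 1L
  i2 <- (as.integer(m1) %% 12L) + 1L
  list(i1 = i1, i2 = i2, w = w, day = day)
}

#' Nitrogen mass-balance derivative
#'
#' Assembles all process fluxes at model day `t`: producer DIN uptake under
#' transmitted light, preference-weighted feeding, excretion, defecation,
#' mortality (linear plus density-dependent top-predator closure with a
#' maritime-mammal interference term), detritus sinking and mineralisation,
#' nitrification, sediment-porewater exchange, ice/snow nutrient entrainment
#' and melt release, atmospheric deposition, river/meltwater input, ocean
#' boundary exchange at driver concentrations, a seasonal migratory-fish
#' presence window, spawning/recruitment transfers between adult and larval
#' pools, and (when non-zero) harvest removal. Driver-derived factors are
#' monthly series interpolated between month midpoints.
#'
#' @param t model day (360-day year, 30-day months).
#' @param state named non-negative numeric vector over [compartment_names()].
#' @param drivers a `driver_set`.
#' @param params a `model_params` list.
#' @param guilds guild table; default [default_guilds()].
#' @param ctx optional precomputed context from the integrator.
#' @param cap_rate maximum specific outflow rate (d^-1) applied to every
#'   donor compartment; the integrator passes a value tied to its step so
#'   fluxes can never drive a pool negative within a step. Default `Inf`.
#' @param closed_boundaries if `TRUE` all import/export channels are forced
#'   to zero (used by conservation checks).
#' @return List with `dstate` (named derivative, mmol N m^-2 d^-1), `flows`
#'   (35 x 35 donor -> recipient matrix), `imports`, `exports` (per
#'   compartment boundary channels) and `demographic` (spawning/recruitment
#'   matrix, excluded from the food-web ledger).
#' @export
state_derivative <- function(t, state, drivers, params,
                             guilds = default_guilds(), ctx = NULL,
                             cap_rate = Inf, closed_boundaries = FALSE) {
  if (any(!is.finite(state))) {
    stop("non-finite state in compartment(s): ",
         paste(compartment_names()[!is.finite(state)], collapse = ", "))
  }
  if (any(state < -1e-8)) {
    stop("negative state in compartment(s): ",
         paste(compartment_names()[state < -1e-8], collapse = ", "))
  }
  state <- pmax(as.numeric(state), 0)
  if (is.null(ctx) || is.null(ctx$rc)) {
    ctx <- build_context(params, guilds, drivers)
  }
  rc <- ctx$rc
  n <- ctx$n
  idx <- ctx$idx
  nn <- n * n
  FL <- numeric(nn); dim(FL) <- c(n, n)
  DM <- numeric(nn); dim(DM) <- c(n, n)

  mw <- month_weights(t)
  i1 <- mw$i1; i2 <- mw$i2; w <- mw$w; w1 <- 1 - w
  ip <- function(v) w1 * v[[i1]] + w * v[[i2]]
  ipr <- function(m) w1 * m[i1, ] + w * m[i2, ]

  imports <- ipr(rc$imp12)
  exports <- ipr(rc$exr12) * state

  # --- producer uptake -------------------------------------------------
  c_sn <- state[[idx[["surface_nitrate"]]]] / rc$v_surf
  c_sa <- state[[idx[["surface_ammonia"]]]] / rc$v_surf
  c_dn <- state[[idx[["deep_nitrate"]]]] / rc$v_deep
  c_da <- state[[idx[["deep_ammonia"]]]] / rc$v_deep
  ivol <- ip(rc$iv12)
  v_ice <- max(rc$min_ice_volume, ivol * rc$brine_fraction)
  c_in <- state[[idx[["ice_nitrate"]]]] / v_ice
  c_ia <- state[[idx[["ice_ammonia"]]]] / v_ice
  uf <- ipr(rc$uptake_fac)
  conc_n <- c(c_sn, c_dn, c_in, c_sn)
  conc_a <- c(c_sa, c_da, c_ia, c_sa)
  pmass <- state[rc$prod_i]
  fac <- uf * pmass
  FL[rc$nit_pair] <- rc$u_n * conc_n / (rc$k_n + conc_n) *
    rc$k_i / (rc$k_i + conc_a) * fac
  FL[rc$amm_pair] <- rc$u_a * conc_a / (rc$k_a + conc_a) * fac

  # first-order transfers (mortality, sinking, mineralisation, nitrification)
  FL[rc$lin_pair] <- FL[rc$lin_pair] + ipr(rc$lin_rate12) * state[rc$lin_d]
  # producer self-limitation (macrophyte self-shading by default)
  FL[rc$prod_mort_pair] <- FL[rc$prod_mort_pair] + rc$prod_dd * pmass * pmass

  # --- feeding ---------------------------------------------------------
  ff <- ipr(rc$feed_fac)
  dd <- ipr(rc$dd_fac)
  cidx <- 0L
  for (cc in ctx$consumers) {
    cidx <- cidx + 1L
    cm <- state[[cc$i]]
    if (cm <= 0) next
    weighted <- cc$pref * state[cc$prey]
    avail <- sum(weighted)
    if (avail > 0) {
      total <- cm * ff[[cidx]] * avail / (cc$k_food + avail)
      fl <- total / avail * weighted
      FL[cc$prey_mat] <- FL[cc$prey_mat] + fl
      FL[cc$i, cc$def] <- FL[cc$i, cc$def] + (1 - cc$assim) * total
      FL[cc$i, cc$exc] <- FL[cc$i, cc$exc] + cc$assim * cc$excr * total
    }
    FL[cc$i, cc$mort] <- FL[cc$i, cc$mort] + cc$mort_lin * cm +
      dd[[cidx]] * cm * cm
  }

  # --- vertical mixing and sediment exchange ---------------------------
  vel_mix <- ip(rc$vel_mix12)
  fl <- vel_mix * (c_dn - c_sn) * rc$aO
  if (fl >= 0) FL[idx[["deep_nitrate"]], idx[["surface_nitrate"]]] <- fl
  else FL[idx[["surface_nitrate"]], idx[["deep_nitrate"]]] <- -fl
  fl <- vel_mix * (c_da - c_sa) * rc$aO
  if (fl >= 0) FL[idx[["deep_ammonia"]], idx[["surface_ammonia"]]] <- fl
  else FL[idx[["surface_ammonia"]], idx[["deep_ammonia"]]] <- -fl

  c_pn <- state[[idx[["porewater_nitrate"]]]] / rc$v_pore
  c_pa <- state[[idx[["porewater_ammonia"]]]] / rc$v_pore
  sedx <- rc$sediment_exchange
  fl <- sedx * (c_pn - c_dn) * rc$aO
  if (fl >= 0) FL[idx[["porewater_nitrate"]], idx[["deep_nitrate"]]] <- fl
  else FL[idx[["deep_nitrate"]], idx[["porewater_nitrate"]]] <- -fl
  fl <- sedx * (c_pa - c_da) * rc$aO
  if (fl >= 0) FL[idx[["porewater_ammonia"]], idx[["deep_ammonia"]]] <- fl
  else FL[idx[["deep_ammonia"]], idx[["porewater_ammonia"]]] <- -fl
  fl <- sedx * (c_pn - c_sn) * rc$aI
  if (fl >= 0) FL[idx[["porewater_nitrate"]], idx[["surface_nitrate"]]] <-
      FL[idx[["porewater_nitrate"]], idx[["surface_nitrate"]]] + fl
  else FL[idx[["surface_nitrate"]], idx[["porewater_nitrate"]]] <- -fl
  fl <- sedx * (c_pa - c_sa) * rc$aI
  if (fl >= 0) FL[idx[["porewater_ammonia"]], idx[["surface_ammonia"]]] <-
      FL[idx[["porewater_ammonia"]], idx[["surface_ammonia"]]] + fl
  else FL[idx[["surface_ammonia"]], idx[["porewater_ammonia"]]] <- -fl

  # --- cryosphere entrainment and melt release -------------------------
  divol <- (rc$iv12[[i2]] - rc$iv12[[i1]]) / 30
  dsvol <- (rc$sv12[[i2]] - rc$sv12[[i1]]) / 30
  if (divol > 0) {
    FL[idx[["surface_nitrate"]], idx[["ice_nitrate"]]] <-
      rc$entrain_eff * divol * c_sn
    FL[idx[["surface_ammonia"]], idx[["ice_ammonia"]]] <-
      rc$entrain_eff * divol * c_sa
    # phytoplankton frozen into new ice seed next season's ice algae
    FL[idx[["surface_phyt"]], idx[["ice_algae"]]] <-
      rc$entrain_eff * divol * state[[idx[["surface_phyt"]]]] / rc$v_surf
  } else if (divol < 0) {
    rel <- rc$melt_release * (-divol) / max(ivol, rc$min_ice_volume)
    FL[idx[["ice_nitrate"]], idx[["surface_nitrate"]]] <-
      rel * state[[idx[["ice_nitrate"]]]]
    FL[idx[["ice_ammonia"]], idx[["surface_ammonia"]]] <-
      rel * state[[idx[["ice_ammonia"]]]]
    FL[idx[["ice_detritus"]], idx[["surface_detritus"]]] <-
      FL[idx[["ice_detritus"]], idx[["surface_detritus"]]] +
      rel * state[[idx[["ice_detritus"]]]]
    FL[idx[["ice_algae"]], idx[["surface_detritus"]]] <-
      FL[idx[["ice_algae"]], idx[["surface_detritus"]]] +
      rel * rc$algae_flush * state[[idx[["ice_algae"]]]]
    melt_din <- (-divol) * ip(rc$meltwater_DIN)
    imports[[idx[["surface_nitrate"]]]] <-
      imports[[idx[["surface_nitrate"]]]] + 0.7 * melt_din
    imports[[idx[["surface_ammonia"]]]] <-
      imports[[idx[["surface_ammonia"]]]] + 0.3 * melt_din
  }
  if (dsvol < 0) {
    svol <- ip(rc$sv12)
    rels <- (-dsvol) / max(svol, 1e-3)
    FL[idx[["snow_nitrate"]], idx[["surface_nitrate"]]] <-
      rels * state[[idx[["snow_nitrate"]]]]
    FL[idx[["snow_ammonia"]], idx[["surface_ammonia"]]] <-
      rels * state[[idx[["snow_ammonia"]]]]
  }

  # migratory fish: relax towards the seasonal boundary target
  mig <- rc$mig
  day <- mw$day
  target <- if (day >= mig$entry_day && day <= mig$exit_day) {
    mig$boundary_stock * mig$presence_fraction
  } else 0
  mflux <- mig$relax_rate * (target - state[[idx[["migratory_fish"]]]])
  if (mflux >= 0) imports[[idx[["migratory_fish"]]]] <- mflux
  else exports[[idx[["migratory_fish"]]]] <- -mflux

  # --- demography (side ledger) ---------------------------------------
  dem <- rc$dem
  dm_any <- FALSE
  spawning <- day >= dem$spawn_start && day <= dem$spawn_end
  recruiting <- day >= dem$recruit_start && day <= dem$recruit_end
  if (spawning || recruiting) {
    dm_any <- TRUE
    for (pr in ctx$pairs) {
      if (spawning) {
        DM[pr[[1L]], pr[[2L]]] <- dem$spawn_rate * state[[pr[[1L]]]]
      }
      if (recruiting) {
        DM[pr[[2L]], pr[[1L]]] <- dem$recruit_rate * state[[pr[[2L]]]]
      }
    }
  }

  # harvest removal (boundary export); skipped entirely at zero activity so
  # a fishing-free run is bitwise identical to one with the terms absent
  if (ctx$any_harvest) {
    h <- ctx$harvest
    li <- idx[names(h)]
    exports[li] <- exports[li] + h * state[li]
  }

  if (closed_boundaries) {
    imports <- numeric(n)
    exports <- numeric(n)
  }

  # donor-limited capping: scale down all outflows of any compartment whose
  # total specific outflow exceeds cap_rate
  out_fl <- .rowSums(FL, n, n)
  out_dm <- if (dm_any) .rowSums(DM, n, n) else numeric(n)
  out_tot <- out_fl + out_dm + exports
  if (is.finite(cap_rate)) {
    lim <- cap_rate * state
    over <- out_tot > lim & out_tot > 0
    if (any(over)) {
      sc <- rep(1, n)
      sc[over] <- lim[over] / out_tot[over]
      FL <- FL * sc
      if (dm_any) DM <- DM * sc
      exports <- exports * sc
      out_tot <- out_tot * sc
      out_dm <- out_dm * sc
    }
  }

  dstate <- .colSums(FL, n, n) - (out_tot - exports - out_dm) +
    imports - exports
  if (dm_any) dstate <- dstate + .colSums(DM, n, n) - out_dm
  names(dstate) <- ctx$cn
  dimnames(FL) <- ctx$dn
  dimnames(DM) <- ctx$dn
  names(imports) <- ctx$cn
  names(exports) <- ctx$cn
  list(dstate = dstate, flows = FL, imports = imports, exports = exports,
       demographic = DM)
}
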