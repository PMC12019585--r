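# Ecological network indices computed from the annually integrated flow
# matrix: nutrition-mode shares, trophic levels, omnivory, internal
# ascendancy/capacity, dominance of indirect effects, F-ratio and production.

#' Construct a flow ledger from a flow matrix
#'
#' Convenience constructor used in examples and tests: wraps a donor ->
#' recipient matrix (rows and columns named over [compartment_names()]
#' subsets) into a `flow_ledger`.
#'
#' @param T square named flow matrix (mmol N m^-2 y^-1).
#' @param imports,exports optional named boundary vectors.
#' @param masses optional named annual mean masses.
#' @return A `flow_ledger`.
#' @export
make_ledger <- function(T, imports = NULL, exports = NULL, masses = NULL) {
  cn <- compartment_names()
  bad <- setdiff(rownames(T), cn)
  if (length(bad)) stop("unknown compartments: ", paste(bad, collapse = ", "))
  TT <- matrix(0, length(cn), length(cn),
               dimnames = list(donor = cn, recipient = cn))
  TT[rownames(T), colnames(T)] <- T
  fill <- function(v) {
    out <- stats::setNames(numeric(length(cn)), cn)
    if (!is.null(v)) out[names(v)] <- v
    out
  }
  structure(list(T = TT, imports = fill(imports), exports = fill(exports),
                 demographic = TT * 0, annual_mean_mass = fill(masses),
                 year_index = NA_integer_),
            class = "flow_ledger")
}

#' Nutrition-mode shares of biological activity
#'
#' Classifies all live flows into three modes and scales them as percentages:
#' primary production (all flows into the producer guilds), recycling
#' (detritivory: flows from detrital compartments, including corpses, into
#' living compartments, excluding flows into producers) and consumption
#' (flows between living compartments, excluding flows into producers).
#'
#' @param ledger a `flow_ledger`.
#' @return Named vector `c(primary_production, recycling, consumption)` in
#'   percent, summing to 100; all `NA` with a warning when there is no live
#'   activity.
#' @export
nutrition_shares <- function(ledger) {
  TT <- ledger$T
  prod <- producer_names()
  det <- detrital_names()
  liv <- living_names()
  consv <- setdiff(liv, prod)
  pp <- sum(TT[, prod])
  rec <- sum(TT[det, consv])
  con <- sum(TT[liv, consv])
  tot <- pp + rec + con
  if (tot <= 0) {
    warning("no live activity in ledger; nutrition shares undefined")
    return(c(primary_production = NA_real_, recycling = NA_real_,
             consumption = NA_real_))
  }
  100 * c(primary_production = pp, recycling = rec, consumption = con) / tot
}

#' Living mass attributed to nutrition modes
#'
#' Producer mass counts as primary production; a consumer's mass is split
#' between recycling and consumption in proportion to its inbound detritivory
#' versus consumption flows (scavengers/omnivores are shared; pure consumers
#' count entirely as consumption). Percentages of total living mass.
#'
#' @param masses named state or annual mean mass vector.
#' @param ledger a `flow_ledger`.
#' @return Named vector in percent, summing to 100.
#' @export
mass_shares_by_mode <- function(masses, ledger) {
  TT <- ledger$T
  prod <- producer_names()
  det <- detrital_names()
  liv <- living_names()
  consv <- setdiff(liv, prod)
  pp_mass <- sum(masses[prod])
  rec_mass <- 0
  con_mass <- 0
  fallback <- character()
  for (j in consv) {
    dj <- sum(TT[det, j])
    cj <- sum(TT[liv, j])
    mj <- masses[[j]]
    if (dj + cj <= 0) {
      if (mj > 0) fallback <- c(fallback, j)
      con_mass <- con_mass + mj
    } else {
      rec_mass <- rec_mass + mj * dj / (dj + cj)
      con_mass <- con_mass + mj * cj / (dj + cj)
    }
  }
  if (length(fallback)) {
    warning("guild(s) with positive mass but no inbound flow assigned by ",
            "category: ", paste(fallback, collapse = ", "))
  }
  tot <- pp_mass + rec_mass + con_mass
  100 * c(primary_production = pp_mass, recycling = rec_mass,
          consumption = con_mass) / tot
}

#' Trophic levels from the flow matrix
#'
#' Diet proportions are the food inflows of each living consumer scaled to
#' sum to one; a consumer's trophic level is one plus the diet-weighted mean
#' trophic level of its food sources. Producers and non-living compartments
#' are anchored at trophic level 1, and the resulting linear system is solved
#' exactly.
#'
#' @param ledger a `flow_ledger`.
#' @return Named numeric vector of trophic levels over all compartments.
#' @export
trophic_levels <- function(ledger) {
  TT <- ledger$T
  cn <- rownames(TT)
  prod <- producer_names()
  consv <- setdiff(living_names(), prod)
  tl <- stats::setNames(rep(1, length(cn)), cn)
  inflow <- colSums(TT[, consv, drop = FALSE])
  active <- consv[inflow > 0]
  if (!length(active)) return(tl)
  P <- sweep(TT[, active, drop = FALSE], 2, colSums(TT[, active, drop = FALSE]),
             "/")  # p_ij: share of j's diet from i
  M <- t(P[active, , drop = FALSE])            # M[j, k] = p_{k -> j}
  b <- 1 + colSums(P[setdiff(cn, active), , drop = FALSE])
  sol <- tryCatch(solve(diag(length(active)) - M, b), error = function(e) {
    stop("diet cycle with no external anchor among: ",
         paste(active, collapse = ", "))
  })
  tl[active] <- sol
  tl
}

#' Omnivory indices
#'
#' Diet-weighted variance of food-source trophic levels around the
#' consumer's own level minus one: `OI_j = sum_i p_ij (TL_i - (TL_j - 1))^2`.
#' Zero for single-source or single-level diets; larger values mean broader
#' feeding across trophic levels.
#'
#' @param ledger a `flow_ledger`.
#' @param TL trophic levels from [trophic_levels()] (computed if missing).
#' @return Named vector of omnivory indices over living consumers.
#' @export
omnivory_indices <- function(ledger, TL = trophic_levels(ledger)) {
  TT <- ledger$T
  consv <- setdiff(living_names(), producer_names())
  oi <- stats::setNames(numeric(length(consv)), consv)
  for (j in consv) {
    inflow <- TT[, j]
    tot <- sum(inflow)
    if (tot <= 0) next
    p <- inflow / tot
    oi[[j]] <- sum(p * (TL - (TL[[j]] - 1))^2)
  }
  oi
}

#' Internal ascendancy and capacity
#'
#' Information-theoretic measures of the realised organisation of the
#' internal flow network (boundary imports and exports excluded), in
#' flow-bits units with logarithms base 2: ascendancy
#' `A = sum T_ij log2(T_ij T.. / (T_i. T_.j))` and capacity
#' `C = -sum T_ij log2(T_ij / T..)`, with `0 <= A <= C`.
#'
#' @param ledger a `flow_ledger`.
#' @return List with `A_internal`, `C_internal`, `AC_ratio` (NA with a
#'   warning when capacity is zero) and `defined`.
#' @export
ascendancy_capacity <- function(ledger) {
  TT <- ledger$T
  tot <- sum(TT)
  if (tot <= 0) {
    warning("empty internal flow matrix; ascendancy/capacity undefined")
    return(list(A_internal = NA_real_, C_internal = NA_real_,
                AC_ratio = NA_real_, defined = FALSE))
  }
  ri <- rowSums(TT)
  cj <- colSums(TT)
  nz <- which(TT > 0, arr.ind = TRUE)
  tij <- TT[nz]
  A <- sum(tij * log2(tij * tot / (ri[nz[, 1]] * cj[nz[, 2]])))
  C <- -sum(tij * log2(tij / tot))
  if (C <= 0) {
    warning("degenerate single-flow network; A/C ratio undefined")
    return(list(A_internal = A, C_internal = C, AC_ratio = NA_real_,
                defined = FALSE))
  }
  list(A_internal = A, C_internal = C, AC_ratio = A / C, defined = TRUE)
}

#' Dominance of indirect effects
#'
#' Flows are normalised by each recipient's total inflow including boundary
#' imports, giving a substochastic matrix `G`; with `N = (I - G)^-1`, the
#' statistic is `sum(N - I - G) / sum(G)`: the mass contribution through
#' pathways of length greater than one relative to the direct flow intensity.
#'
#' @param ledger a `flow_ledger`.
#' @return Scalar dominance ratio.
#' @export
indirect_effects_dominance <- function(ledger) {
  TT <- ledger$T
  denom <- colSums(TT) + ledger$imports
  G <- sweep(TT, 2, pmax(denom, .Machine$double.eps), "/")
  G[, denom <= 0] <- 0
  ev <- max(Mod(eigen(G, only.values = TRUE)$values))
  if (ev >= 1) {
    stop("non-dissipative flow network: spectral radius ", format(ev), " >= 1")
  }
  N <- solve(diag(nrow(G)) - G)
  direct <- sum(G)
  if (direct <= 0) return(0)
  sum(N - diag(nrow(G)) - G) / direct
}

#' Producer F-ratio
#'
#' Fraction of the producers' dissolved inorganic nitrogen uptake taken as
#' nitrate — a measure of new (non-recycled) production.
#'
#' @param ledger a `flow_ledger`.
#' @return Scalar in \[0,1\]; `NA` with a warning when there is no uptake.
#' @export
f_ratio <- function(ledger) {
  TT <- ledger$T
  prod <- producer_names()
  nit <- sum(TT[nitrate_pool_names(), prod])
  amm <- sum(TT[ammonia_pool_names(), prod])
  if (nit + amm <= 0) {
    warning("no producer DIN uptake; F-ratio undefined")
    return(NA_real_)
  }
  nit / (nit + amm)
}

#' Net primary production and secondary production
#'
#' `npp` is producer DIN uptake minus all producer loss flows to
#' non-producer compartments (grazing, mortality, melt flushing), so it is
#' positive when the producers are a net source to the rest of the web — the
#' package's documented sign convention. `secondary_production` sums, over
#' all non-producer living guilds, assimilated intake net of excretion:
#' `intake * assimilation * (1 - excretion fraction)`.
#'
#' @param ledger a `flow_ledger`.
#' @param params a `model_params` list (assimilation/excretion fractions).
#' @return Named vector `c(npp = , secondary_production = )` in
#'   mmol N m^-2 y^-1.
#' @export
production_metrics <- function(ledger, params) {
  TT <- ledger$T
  prod <- producer_names()
  consv <- setdiff(living_names(), prod)
  uptake <- sum(TT[c(nitrate_pool_names(), ammonia_pool_names()), prod])
  losses <- sum(TT[prod, setdiff(colnames(TT), prod)])
  intake <- colSums(TT[, consv, drop = FALSE])
  sp <- sum(intake * params$feeding$assim[consv] *
              (1 - params$feeding$excr[consv]))
  c(npp = uptake - losses, secondary_production = sp)
}

#' Full network index set
#'
#' Assembles every reported index for one run: trophic levels and omnivory,
#' internal ascendancy/capacity, dominance of indirect effects, flow and mass
#' nutrition shares, the mass-weighted mean trophic level of the four
#' top-predator guilds, the mass-weighted mean omnivory index over all
#' consumer guilds, the F-ratio, and net primary and secondary production.
#'
#' @param ledger a `flow_ledger`.
#' @param masses named annual mean masses (defaults to the ledger's).
#' @param params a `model_params` list.
#' @return List of class `network_index_set`.
#' @export
summary_indices <- function(ledger, masses = ledger$annual_mean_mass,
                            params = default_params()) {
  TL <- trophic_levels(ledger)
  OI <- omnivory_indices(ledger, TL)
  ac <- ascendancy_capacity(ledger)
  top <- top_predator_names()
  consv <- setdiff(living_names(), producer_names())
  wtop <- masses[top]
  mean_tl_top <- if (sum(wtop) > 0) sum(wtop * TL[top]) / sum(wtop) else NA_real_
  wcons <- masses[consv]
  mean_oi <- if (sum(wcons) > 0) sum(wcons * OI[consv]) / sum(wcons) else NA_real_
  pm <- production_metrics(ledger, params)
  structure(list(
    TL = TL, OI = OI,
    A_internal = ac$A_internal, C_internal = ac$C_internal,
    AC_ratio = ac$AC_ratio,
    indirect_dominance = indirect_effects_dominance(ledger),
    shares_flow = nutrition_shares(ledger),
    shares_mass = mass_shares_by_mode(masses, ledger),
    mean_TL_top_predators = mean_tl_top,
    mean_OI_consumers = mean_oi,
    f_ratio = f_ratio(ledger),
    npp = pm[["npp"]],
    secondary_production = pm[["secondary_production"]]
  ), class = "network_index_set")
}

#' Write a network index set as a flat key/value table
#'
#' @param indices a `network_index_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_indices <- function(indices, path) {
  scal <- c("A_internal", "C_internal", "AC_ratio", "indirect_dominance",
            "mean_TL_top_predators", "mean_OI_consumers", "f_ratio", "npp",
            "secondary_production")
  rows <- data.frame(key = character(), value = numeric())
  for (k in scal) rows <- rbind(rows, data.frame(key = k, value = indices[[k]]))
  for (k in names(indices$shares_flow)) {
    rows <- rbind(rows, data.frame(key = paste0("share_flow.", k),
                                   value = indices$shares_flow[[k]]))
  }
  for (k in names(indices$shares_mass)) {
    rows <- rbind(rows, data.frame(key = paste0("share_mass.", k),
                                   value = indices$shares_mass[[k]]))
  }
  for (k in names(indices$TL)) {
    rows <- rbind(rows, data.frame(key = paste0("TL.", k),
                                   value = indices$TL[[k]]))
  }
  for (k in names(indices$OI)) {
    rows <- rbind(rows, data.frame(key = paste0("OI.", k),
                                   value = indices$OI[[k]]))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
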