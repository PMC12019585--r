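#' Run the decadal scenario and knock-out grid
#'
#' For every combination of experiment and decade: generate the scenario
#' drivers, copy the experiment's held variables from the baseline decade,
#' apply any parameter overrides (the attenuation experiment zeroes the
#' ice/snow attenuation coefficients and the albedo), run the system to its
#' steady annual cycle, and record annual mean masses, the network index set
#' and secondary production. Within one experiment, each decade starts from
#' the previous decade's steady state (the first from `state0`), which
#' shortens convergence without changing the attractor.
#'
#' @param config a [scenario_config()].
#' @param params a `model_params` list.
#' @param experiments list of [experiment_spec()] objects (or experiment
#'   names).
#' @param decades integer vector of decade indices (default all).
#' @param state0 initial state for the first decade of each experiment.
#' @param tol,max_years,step integrator controls passed to
#'   [run_to_steady_state()].
#' @return Object of class `experiment_grid`: list with `masses` (long data
#'   frame: experiment, decade, compartment, annual mean mass, converged),
#'   `runs` (named list of `steady_state_result`), `indices` (named list of
#'   `network_index_set`).
#' @export
run_experiment_grid <- function(config, params,
                                experiments = list("full_climate"),
                                decades = seq_len(config$n_decades) - 1L,
                                state0 = reference_state("GL_2010s"),
                                tol = 1e-4, max_years = 50, step = 0.5) {
  experiments <- lapply(experiments, function(e) {
    if (is.character(e)) experiment_spec(e) else e
  })
  baseline <- generate_decadal_drivers(config, config$baseline_decade)
  rows <- list()
  runs <- list()
  indices <- list()
  for (ex in experiments) {
    pars <- params
    if (length(ex$param_overrides)) {
      fl <- flatten_params(pars)
      fl[names(ex$param_overrides)] <- ex$param_overrides
      pars <- unflatten_params(fl, pars)
    }
    x0 <- state0
    for (d in decades) {
      drv <- generate_decadal_drivers(config, d)
      drv <- apply_knockout(drv, baseline, ex)
      res <- run_to_steady_state(x0, drv, pars, tol = tol,
                                 max_years = max_years, step = step,
                                 keep_trajectory = FALSE)
      x0 <- res$state_end
      key <- paste0(ex$name, ".decade_", d)
      runs[[key]] <- res
      indices[[key]] <- summary_indices(res$ledger, params = pars)
      m <- res$ledger$annual_mean_mass
      rows[[key]] <- data.frame(
        experiment = ex$name, decade = d, compartment = names(m),
        mass = unname(m), converged = res$converged, row.names = NULL)
    }
  }
  structure(list(masses = do.call(rbind, c(rows, make.row.names = FALSE)),
                 runs = runs, indices = indices),
            class = "experiment_grid")
}

#' Guild mass change table
#'
#' Percentage change and log10 mass ratio of each guild between a baseline
#' and a scenario state. Guilds with zero baseline mass are flagged and get
#' `NA` in the log column.
#'
#' @param baseline_masses,scenario_masses named mass vectors on the same
#'   inventory.
#' @return Data frame with columns `guild`, `percent_change`, `log10_ratio`,
#'   `flagged`.
#' @export
#' @examples
#' inv <- load_mass_fixture()
#' b <- stats::setNames(inv$GL_2010s, inv$compartment)
#' s <- stats::setNames(inv$GL_2050s, inv$compartment)
#' ct <- change_table(b, s)
#' round(ct[ct$guild == "Maritime mammals", "percent_change"])
change_table <- function(baseline_masses, scenario_masses) {
  stopifnot(identical(names(baseline_masses), names(scenario_masses)))
  zero <- baseline_masses <= 0
  pct <- 100 * (scenario_masses / baseline_masses - 1)
  lr <- log10(scenario_masses / baseline_masses)
  pct[zero] <- NA_real_
  lr[zero] <- NA_real_
  data.frame(guild = names(baseline_masses),
             percent_change = unname(pct),
             log10_ratio = unname(lr),
             flagged = unname(zero), row.names = NULL)
}

#' Change in nutrient mass locked in snow and ice
#'
#' Percentage change of the summed snow nitrate, snow ammonia, ice nitrate
#' and ice ammonia pools between two states. Accepts either internal state
#' vectors or vectors named with the display labels of the reference
#' inventory.
#'
#' @param masses_baseline,masses_future named mass vectors.
#' @return Scalar percent change.
#' @export
snow_ice_nutrient_change <- function(masses_baseline, masses_future) {
  keys <- c("snow_nitrate", "snow_ammonia", "ice_nitrate", "ice_ammonia")
  pick <- function(m) {
    if (all(keys %in% names(m))) sum(m[keys])
    else sum(m[report_label(keys)])
  }
  b <- pick(masses_baseline)
  f <- pick(masses_future)
  100 * (f / b - 1)
}

#' Principal component analysis of steady-state masses
#'
#' Standardises compartment masses to zero mean and unit variance across
#' runs (dropping zero-variance compartments with a warning) and
#' eigen-decomposes their correlation structure. Components carry a
#' deterministic sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param table an `experiment_grid` or its long `masses` data frame.
#' @return List of class `pca_result`: `scores` (runs x components),
#'   `loadings` (compartments x components), `variance_fraction`.
#' @export
pca_states <- function(table) {
  df <- if (inherits(table, "experiment_grid")) table$masses else table
  wide <- stats::reshape(
    df[, c("experiment", "decade", "compartment", "mass")],
    idvar = c("experiment", "decade"), timevar = "compartment",
    direction = "wide")
  run_id <- paste0(wide$experiment, ".decade_", wide$decade)
  m <- as.matrix(wide[, -(1:2)])
  colnames(m) <- sub("^mass\\.", "", colnames(m))
  rownames(m) <- run_id
  if (nrow(m) < 2) stop("need at least 2 runs for PCA")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance compartment(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf, center = pc$center,
                 scale = pc$scale),
            class = "pca_result")
}
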