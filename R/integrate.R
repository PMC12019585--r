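#' Integrate one annual driver cycle
#'
#' Fixed-step fourth-order Runge-Kutta integration over the 360-day model
#' year (12 x 30-day months), accumulating the annually integrated flow
#' ledger. Every stage derivative is donor-limited (total specific outflow of
#' a compartment capped at `0.8/step` per day) so pools cannot be driven
#' negative within a step. The ledger is accumulated with the same
#' Runge-Kutta weights as the state update, so for each compartment
#' `inflows - outflows - net boundary - net demographic` equals its mass
#' change over the year to round-off.
#'
#' @param state0 named state vector over [compartment_names()].
#' @param drivers a `driver_set`.
#' @param params a `model_params` list.
#' @param step time step in days (must be <= 1).
#' @param guilds guild table.
#' @param ctx optional precomputed derivative context.
#' @param closed_boundaries force all boundary channels to zero.
#' @return List with `state_end` and `ledger` (class `flow_ledger`): fields
#'   `T` (annually integrated donor -> recipient flows, mmol N m^-2 y^-1,
#'   demographic transfers excluded), `imports`, `exports`, `demographic`,
#'   `annual_mean_mass`, `year_index`.
#' @export
integrate_annual_cycle <- function(state0, drivers, params, step = 0.25,
                                   guilds = default_guilds(), ctx = NULL,
                                   closed_boundaries = FALSE) {
  if (step > 1) stop("step must be at most 1 day")
  cn <- compartment_names()
  stopifnot(length(state0) == length(cn))
  x <- stats::setNames(as.numeric(state0), cn)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("invalid initial state in: ",
         paste(cn[!is.finite(x) | x < 0], collapse = ", "))
  }
  if (is.null(ctx)) ctx <- build_context(params, guilds, drivers)
  n <- length(cn)
  TT <- matrix(0, n, n, dimnames = list(donor = cn, recipient = cn))
  DD <- matrix(0, n, n, dimnames = list(donor = cn, recipient = cn))
  imp <- stats::setNames(numeric(n), cn)
  exp_ <- stats::setNames(numeric(n), cn)
  mean_mass <- stats::setNames(numeric(n), cn)
  cap <- 0.8 / step
  nsteps <- round(360 / step)
  h <- 360 / nsteps
  t <- 0
  for (s in seq_len(nsteps)) {
    k1 <- state_derivative(t, x, drivers, params, guilds, ctx, cap,
                           closed_boundaries)
    k2 <- state_derivative(t + h / 2, pmax(x + h / 2 * k1$dstate, 0), drivers,
                           params, guilds, ctx, cap, closed_boundaries)
    k3 <- state_derivative(t + h / 2, pmax(x + h / 2 * k2$dstate, 0), drivers,
                           params, guilds, ctx, cap, closed_boundaries)
    k4 <- state_derivative(t + h, pmax(x + h * k3$dstate, 0), drivers,
                           params, guilds, ctx, cap, closed_boundaries)
    mean_mass <- mean_mass + x * (h / 360)
    w <- h / 6
    x_new <- x + w * (k1$dstate + 2 * k2$dstate + 2 * k3$dstate + k4$dstate)
    if (any(!is.finite(x_new))) {
      stop("integration became unstable at day ", round(t, 2),
           " in compartment(s): ",
           paste(cn[!is.finite(x_new)], collapse = ", "))
    }
    TT <- TT + w * (k1$flows + 2 * k2$flows + 2 * k3$flows + k4$flows)
    DD <- DD + w * (k1$demographic + 2 * k2$demographic + 2 * k3$demographic +
                      k4$demographic)
    imp <- imp + w * (k1$imports + 2 * k2$imports + 2 * k3$imports +
                        k4$imports)
    exp_ <- exp_ + w * (k1$exports + 2 * k2$exports + 2 * k3$exports +
                          k4$exports)
    x <- x_new
    x[x < 0 & x > -1e-9] <- 0
    if (any(x < 0)) {
      stop("negative mass at day ", round(t + h, 2), " in compartment(s): ",
           paste(cn[x < 0], collapse = ", "))
    }
    t <- t + h
  }
  ledger <- structure(
    list(T = TT, imports = imp, exports = exp_, demographic = DD,
         annual_mean_mass = mean_mass, year_index = 1L),
    class = "flow_ledger")
  list(state_end = x, ledger = ledger)
}

#' Run the model to its steady annual cycle
#'
#' Repeats [integrate_annual_cycle()] with identical drivers each year until
#' the maximum relative year-on-year change of the annual mean masses falls
#' below `tol`, or `max_years` is reached. The attractor under fixed
#' climatological forcing is a repeating annual cycle, which removes the
#' influence of the initial state.
#'
#' @inheritParams integrate_annual_cycle
#' @param tol convergence tolerance on the maximum relative change of annual
#'   mean masses (denominator floored at 0.01 mmol N m^-2, so near-empty
#'   pools are judged on absolute change and do not dominate).
#' @param max_years cap on the number of simulated years.
#' @param keep_trajectory if `TRUE` (default) keep the per-year annual mean
#'   masses.
#' @return Object of class `steady_state_result`: `ledger` (final year),
#'   `state_end`, `converged`, `years_run`, `convergence_metric`,
#'   `trajectory` (years x compartments matrix).
#' @export
run_to_steady_state <- function(state0, drivers, params, tol = 1e-6,
                                max_years = 200, step = 0.25,
                                guilds = default_guilds(),
                                keep_trajectory = TRUE) {
  if (tol <= 0) stop("tol must be positive")
  ctx <- build_context(params, guilds, drivers)
  x <- state0
  prev <- NULL
  traj <- if (keep_trajectory) list() else NULL
  metric <- Inf
  year <- 0L
  res <- NULL
  while (year < max_years) {
    year <- year + 1L
    res <- integrate_annual_cycle(x, drivers, params, step, guilds, ctx)
    x <- res$state_end
    m <- res$ledger$annual_mean_mass
    if (keep_trajectory) traj[[year]] <- m
    if (!is.null(prev)) {
      metric <- max(abs(m - prev) / pmax(prev, 1e-2))
      if (metric <= tol) break
    }
    prev <- m
  }
  res$ledger$year_index <- year
  structure(list(
    ledger = res$ledger, state_end = x,
    converged = is.finite(metric) && metric <= tol,
    years_run = year, convergence_metric = metric,
    trajectory = if (keep_trajectory) do.call(rbind, traj) else NULL
  ), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result> ", x$years_run, " year(s), ",
      if (x$converged) "converged" else "NOT converged",
      " (metric ", format(x$convergence_metric, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Persist steady-state outputs as delimited tables
#'
#' Writes the annual mean masses (guild, value) and the flow matrix in long
#' format (donor, recipient, annual flow) for standalone use of the index
#' calculators.
#'
#' @param result a `steady_state_result`.
#' @param mass_path,flow_path output CSV paths (either may be `NULL`).
#' @return Invisibly, a list of the paths written.
#' @export
write_steady_state <- function(result, mass_path = NULL, flow_path = NULL) {
  if (!is.null(mass_path)) {
    m <- result$ledger$annual_mean_mass
    utils::write.csv(data.frame(compartment = names(m),
                                label = unname(report_label(names(m))),
                                annual_mean_mass = unname(m)),
                     mass_path, row.names = FALSE)
  }
  if (!is.null(flow_path)) {
    TT <- result$ledger$T
    nz <- which(TT > 0, arr.ind = TRUE)
    utils::write.csv(data.frame(donor = rownames(TT)[nz[, 1]],
                                recipient = colnames(TT)[nz[, 2]],
                                flow = TT[nz]),
                     flow_path, row.names = FALSE)
  }
  invisible(list(mass = mass_path, flow = flow_path))
}

#' Read a long-format flow matrix into a ledger
#'
#' Accepts the CSV written by [write_steady_state()] (or any long table with
#' columns donor, recipient, flow over the compartment inventory) and builds
#' a minimal `flow_ledger` suitable for the network-index calculators.
#'
#' @param path CSV path.
#' @param masses optional named annual mean masses.
#' @return A `flow_ledger`.
#' @export
read_flow_matrix <- function(path, masses = NULL) {
  long <- utils::read.csv(path)
  cn <- compartment_names()
  bad <- setdiff(unique(c(long$donor, long$recipient)), cn)
  if (length(bad)) stop("unknown compartments: ", paste(bad, collapse = ", "))
  TT <- matrix(0, length(cn), length(cn),
               dimnames = list(donor = cn, recipient = cn))
  TT[cbind(match(long$donor, cn), match(long$recipient, cn))] <- long$flow
  if (is.null(masses)) masses <- stats::setNames(numeric(length(cn)), cn)
  structure(list(T = TT, imports = stats::setNames(numeric(length(cn)), cn),
                 exports = stats::setNames(numeric(length(cn)), cn),
                 demographic = TT * 0, annual_mean_mass = masses,
                 year_index = NA_integer_),
            class = "flow_ledger")
}
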