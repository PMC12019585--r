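#' Parameter space for sensitivity screening
#'
#' Builds the one-row-per-parameter table over the full flattened model
#' parameter set: name, family tag, nominal value and bounds (default +/-20%
#' of nominal). Parameters with zero nominal value (for example harvest
#' ratios with fishing at zero) get zero-width bounds and are held fixed by
#' the design, so their elementary effects are exactly zero.
#'
#' @param params a `model_params` list.
#' @param rel_range half-width of the bounds relative to nominal.
#' @param levels number of grid levels p (even).
#' @return Data frame of class `param_space` with columns `name`, `family`,
#'   `nominal`, `lower`, `upper`, and attribute `levels`.
#' @export
param_space <- function(params = default_params(), rel_range = 0.2,
                        levels = 4L) {
  x <- flatten_params(params)
  sp <- data.frame(name = names(x), family = param_family(names(x)),
                   nominal = unname(x),
                   lower = unname(x - rel_range * abs(x)),
                   upper = unname(x + rel_range * abs(x)),
                   row.names = NULL)
  # keep bounds physically admissible
  frac_upper1 <- grepl("\\.(assim|excr|albedo|entrain_eff|brine_fraction|algae_flush|presence_fraction|sediment_porosity|area_inshore|area_offshore)",
                       sp$name) | grepl("^harvest\\.", sp$name)
  sp$upper[frac_upper1] <- pmin(1, sp$upper[frac_upper1])
  q10 <- grepl("\\.q10", sp$name)
  sp$lower[q10] <- pmax(1, sp$lower[q10])
  if (any(sp$lower > sp$upper)) stop("degenerate bounds: lower > upper")
  attr(sp, "levels") <- as.integer(levels)
  class(sp) <- c("param_space", "data.frame")
  sp
}

#' Morris one-at-a-time sampling plan
#'
#' Generates `r` randomised trajectories on a `p`-level grid in the unit
#' hypercube with step `delta = p / (2(p-1))`. Each trajectory starts from a
#' random admissible grid point and perturbs every parameter exactly once,
#' in random order and random direction, giving `r * (k+1)` model
#' evaluations. Parameters with zero-width bounds stay at their nominal
#' value throughout. Deterministic given `seed`.
#'
#' @param space a [param_space()].
#' @param r number of trajectories (>= 2).
#' @param seed integer seed.
#' @return List of class `morris_plan`: `unit` (points in unit coordinates,
#'   `r*(k+1)` x k), `mapped` (points on parameter scale), `delta`, `order`
#'   and `sign` matrices (r x k), `space`, `r`, `seed`.
#' @export
morris_design <- function(space, r, seed) {
  if (r < 2) stop("r must be at least 2")
  p <- attr(space, "levels")
  if (is.null(p) || p %% 2 != 0) stop("levels p must be even")
  k <- nrow(space)
  delta <- p / (2 * (p - 1))
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old))
  set.seed(as.integer(seed) %% 2147483647L)
  base_levels <- (seq_len(p / 2) - 1) / (p - 1)  # levels with room for +delta
  unit <- matrix(0, r * (k + 1), k, dimnames = list(NULL, space$name))
  ord <- matrix(0L, r, k)
  sgn <- matrix(0L, r, k)
  for (tr in seq_len(r)) {
    b <- sample(base_levels, k, replace = TRUE)
    d <- sample(c(-1L, 1L), k, replace = TRUE)
    start <- ifelse(d > 0, b, b + delta)
    o <- sample.int(k)
    ord[tr, ] <- o
    sgn[tr, ] <- d
    x <- start
    row0 <- (tr - 1L) * (k + 1L)
    unit[row0 + 1L, ] <- x
    for (j in seq_len(k)) {
      pj <- o[[j]]
      x[[pj]] <- x[[pj]] + d[[pj]] * delta
      unit[row0 + 1L + j, ] <- x
    }
  }
  width <- space$upper - space$lower
  mapped <- sweep(sweep(unit, 2, width, "*"), 2, space$lower, "+")
  fixed <- width == 0
  if (any(fixed)) mapped[, fixed] <- matrix(space$nominal[fixed],
                                            nrow(mapped), sum(fixed),
                                            byrow = TRUE)
  structure(list(unit = unit, mapped = mapped, delta = delta, order = ord,
                 sign = sgn, space = space, r = as.integer(r),
                 seed = as.integer(seed)),
            class = "morris_plan")
}

#' Elementary effects from evaluated plan outputs
#'
#' For each trajectory and parameter, the elementary effect is the output
#' difference across that parameter's move divided by the signed step
#' `delta` in unit coordinates. Per parameter the mean, mean absolute value,
#' standard deviation and standard error (`sd/sqrt(r)`) of the effects are
#' reported; a parameter is flagged significant when a two-sided one-sample
#' t test of its mean effect against zero rejects at alpha = 0.05 (a
#' zero-variance, non-zero mean is significant by convention).
#'
#' @param plan a `morris_plan`.
#' @param outputs numeric vector of model outputs, one per plan row; `NA`
#'   marks a missing (failed) evaluation, whose two adjacent effects are
#'   dropped.
#' @param alpha significance level of the t test.
#' @return Data frame of class `morris_result`: per parameter `mean_effect`,
#'   `mean_abs_effect`, `sd_effect`, `se_effect`, `n_effects`,
#'   `significant`; attributes `r`, `delta`, `seed`, `n_missing`.
#' @export
morris_effects <- function(plan, outputs, alpha = 0.05) {
  k <- nrow(plan$space)
  r <- plan$r
  if (length(outputs) != r * (k + 1)) {
    stop("outputs length ", length(outputs), " does not match plan size ",
         r * (k + 1))
  }
  ee <- matrix(NA_real_, r, k, dimnames = list(NULL, plan$space$name))
  for (tr in seq_len(r)) {
    row0 <- (tr - 1L) * (k + 1L)
    for (j in seq_len(k)) {
      pj <- plan$order[tr, j]
      y0 <- outputs[[row0 + j]]
      y1 <- outputs[[row0 + j + 1L]]
      ee[tr, pj] <- (y1 - y0) / (plan$sign[tr, pj] * plan$delta)
    }
  }
  res <- data.frame(
    name = plan$space$name, family = plan$space$family,
    mean_effect = apply(ee, 2, function(v) mean(v, na.rm = TRUE)),
    mean_abs_effect = apply(ee, 2, function(v) mean(abs(v), na.rm = TRUE)),
    sd_effect = apply(ee, 2, function(v) {
      n <- sum(!is.na(v)); if (n >= 2) stats::sd(v, na.rm = TRUE) else NA_real_
    }),
    n_effects = apply(ee, 2, function(v) sum(!is.na(v))),
    row.names = NULL)
  res$se_effect <- res$sd_effect / sqrt(res$n_effects)
  res$significant <- vapply(seq_len(k), function(i) {
    v <- ee[, i]
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA)
    m <- mean(v)
    # effects constant to round-off: significant iff the common value is
    # non-zero (the t statistic is degenerate there)
    if (stats::sd(v) <= 1e-12 * max(abs(m), 1)) return(m != 0)
    stats::t.test(v, mu = 0)$p.value < alpha
  }, logical(1))
  res$mean_effect[res$n_effects == 0] <- NA_real_
  attr(res, "r") <- r
  attr(res, "delta") <- plan$delta
  attr(res, "seed") <- plan$seed
  attr(res, "n_missing") <- sum(is.na(outputs))
  class(res) <- c("morris_result", "data.frame")
  res
}

#' Morris screening of the full model
#'
#' Runs the elementary-effects screening of every model parameter against a
#' steady-state output metric: the producer F-ratio or net primary
#' production. Each plan point rebuilds the parameter set and integrates
#' annual cycles until the output metric itself is stable year-on-year
#' (relative change at most `tol`), the screening-grade convergence
#' criterion: the reported quantity equilibrates much faster than the
#' slowest (top-predator) pools, whose residual drift is irrelevant to the
#' metric. Evaluations chain along each trajectory (adjacent plan points
#' differ in a single parameter, so the previous end state is the natural
#' initial condition), and a move along a fixed (zero-width) parameter
#' reuses the previous output, making its elementary effect exactly zero.
#' Evaluations whose metric does not stabilise within `max_years` are
#' recorded as missing and excluded, with a count.
#'
#' @param params baseline `model_params`.
#' @param drivers a `driver_set` (the baseline decade).
#' @param metric `"f_ratio"` or `"npp"`.
#' @param r number of trajectories.
#' @param seed integer seed for the design.
#' @param space optional [param_space()] (default over `params`).
#' @param state0 initial state for the baseline warm-up run.
#' @param tol relative year-on-year stability tolerance on the metric.
#' @param max_years cap on years per screening evaluation.
#' @param step integrator step (days).
#' @param warm_years years of baseline warm-up shared by all evaluations.
#' @param progress print a progress line every 50 evaluations.
#' @return A `morris_result` (see [morris_effects()]); attribute
#'   `n_nonconverged` counts excluded evaluations, attribute
#'   `baseline_metric` holds the metric of the warm-up run.
#' @export
run_sensitivity <- function(params, drivers, metric = c("f_ratio", "npp"),
                            r = 4, seed = 1L, space = param_space(params),
                            state0 = reference_state("GL_2010s"),
                            tol = 5e-3, max_years = 10, step = 1,
                            warm_years = 10, progress = FALSE) {
  metric <- match.arg(metric)
  metric_of <- function(ledger, pars) {
    if (metric == "f_ratio") f_ratio(ledger)
    else production_metrics(ledger, pars)[["npp"]]
  }
  eval_point <- function(pars, x0) {
    ctx <- build_context(pars, default_guilds(), drivers)
    prev <- NULL
    for (yr in seq_len(max_years)) {
      res <- integrate_annual_cycle(x0, drivers, pars, step,
                                    ctx = ctx)
      x0 <- res$state_end
      m <- metric_of(res$ledger, pars)
      if (!is.null(prev) && is.finite(m) &&
          abs(m - prev) <= tol * max(abs(prev), 1e-6)) {
        return(list(metric = m, state = x0, converged = TRUE))
      }
      prev <- m
    }
    list(metric = prev, state = x0, converged = FALSE)
  }

  warm <- run_to_steady_state(state0, drivers, params, tol = tol,
                              max_years = warm_years, step = step,
                              keep_trajectory = FALSE)
  base <- eval_point(params, warm$state_end)
  plan <- morris_design(space, r, seed)
  n_eval <- nrow(plan$mapped)
  k <- nrow(space)
  outputs <- rep(NA_real_, n_eval)
  n_nonconv <- 0L
  x0 <- base$state
  for (i in seq_len(n_eval)) {
    new_traj <- (i - 1L) %% (k + 1L) == 0L
    if (new_traj) x0 <- base$state  # new trajectory
    # a move along a zero-width (fixed) parameter leaves the model unchanged:
    # reuse the previous output so its elementary effect is exactly zero
    if (!new_traj && identical(plan$mapped[i, ], plan$mapped[i - 1L, ])) {
      outputs[[i]] <- outputs[[i - 1L]]
      next
    }
    fl_i <- flatten_params(params)
    fl_i[plan$space$name] <- plan$mapped[i, ]
    pars_i <- unflatten_params(fl_i, params)
    res <- tryCatch(eval_point(pars_i, x0), error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      n_nonconv <- n_nonconv + 1L
    } else {
      outputs[[i]] <- res$metric
      x0 <- res$state  # adjacent plan points differ in one parameter
    }
    if (progress && i %% 50 == 0) {
      message("morris: ", i, "/", n_eval, " evaluations")
    }
  }
  out <- morris_effects(plan, outputs)
  attr(out, "n_nonconverged") <- n_nonconv
  attr(out, "baseline_metric") <- base$metric
  out
}

#' Write a sensitivity report table
#'
#' @param result a `morris_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
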