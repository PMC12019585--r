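test_that("baseline decade has perennial ice and the final decade opens up", {
  cfg <- scenario_config()
  d0 <- generate_decadal_drivers(cfg, 0)
  d4 <- generate_decadal_drivers(cfg, cfg$n_decades - 1)
  expect_true(all(d0[, "SO_IceCover"] > 0.5))
  expect_true(all(d0[, "SI_IceCover"] > 0.5))
  expect_lt(min(d4[, "SO_IceCover"]), 0.01)
  # at least three consecutive open summer months
  open <- d4[, "SO_IceCover"] < 0.01
  runs <- rle(open)
  expect_gte(max(runs$lengths[runs$values]), 3)
})

test_that("temperature trend is exactly linear in decade index", {
  cfg <- scenario_config()
  d0 <- generate_decadal_drivers(cfg, 0)
  d4 <- generate_decadal_drivers(cfg, 4)
  expect_equal(d4[, "SO_temp"] - d0[, "SO_temp"],
               rep(4 * cfg$warming_per_decade, 12))
  expect_equal(d4[, "D_temp"] - d0[, "D_temp"],
               rep(4 * cfg$warming_per_decade, 12))
})

test_that("driver sets respect physical invariants and polar night", {
  cfg <- scenario_config()
  for (d in 0:(cfg$n_decades - 1)) {
    dr <- generate_decadal_drivers(cfg, d)
    frac <- dr[, c("SO_IceFree", "SI_IceFree", "SO_IceCover", "SI_IceCover")]
    expect_true(all(frac >= 0 & frac <= 1))
    nonneg <- dr[, c("SO_IceThickness", "SI_SnowThickness", "Slight",
                     "SO_nitrate", "D_detritus", "river_volume",
                     "vertical_diffusivity", "SPM_inshore")]
    expect_true(all(nonneg >= 0))
    # ice cover vanishes wherever thickness does
    expect_true(all(dr[, "SO_IceCover"][dr[, "SO_IceThickness"] == 0] == 0))
  }
  # polar night at 76N: irradiance is zero in midwinter months
  d0 <- generate_decadal_drivers(cfg, 0)
  expect_equal(unname(d0[c(1, 12), "Slight"]), c(0, 0))
})

test_that("generation is deterministic and trends are monotone", {
  cfg <- scenario_config()
  expect_identical(generate_decadal_drivers(cfg, 2),
                   generate_decadal_drivers(cfg, 2))
  ann_temp <- vapply(0:4, function(d) {
    mean(generate_decadal_drivers(cfg, d)[, "SO_temp"])
  }, numeric(1))
  ann_ice <- vapply(0:4, function(d) {
    mean(generate_decadal_drivers(cfg, d)[, "SO_IceCover"])
  }, numeric(1))
  expect_true(all(diff(ann_temp) > 0))
  expect_true(all(diff(ann_ice) < 0))
})

test_that("invalid scenario configurations and decades are rejected", {
  expect_error(scenario_config(n_decades = 0), "n_decades")
  expect_error(scenario_config(latitude = 30), "latitude")
  expect_error(scenario_config(warming_per_decade = -1), "non-negative")
  expect_error(generate_decadal_drivers(scenario_config(), 7), "out of range")
})

test_that("knock-outs copy exactly the held variables from the baseline", {
  cfg <- scenario_config()
  b <- generate_decadal_drivers(cfg, 0)
  x <- generate_decadal_drivers(cfg, 4)
  # empty knock-out leaves the scenario unchanged
  expect_equal(apply_knockout(x, b, experiment_spec("full_climate")), x)
  # holding everything returns the baseline
  all_held <- structure(list(name = "all", held_variables = driver_names(),
                             param_overrides = numeric(), decade = 0L),
                        class = "experiment_spec")
  expect_equal(unclass(apply_knockout(x, b, all_held))[, ],
               unclass(b)[, ])
  # ice experiment: cryosphere series from baseline, temperature from scenario
  ko <- apply_knockout(x, b, experiment_spec("ice"))
  for (v in c("SO_IceFree", "SI_IceFree", "SO_IceCover", "SI_IceCover",
              "SO_IceThickness", "SI_IceThickness", "SO_SnowThickness",
              "SI_SnowThickness")) {
    expect_equal(ko[, v], b[, v], info = v)
  }
  expect_equal(ko[, "SO_temp"], x[, "SO_temp"])
  # idempotence
  expect_equal(apply_knockout(ko, b, experiment_spec("ice")), ko)
  # unknown held variable errors
  bad <- experiment_spec("light")
  bad$held_variables <- c("Slight", "NotAVariable")
  expect_error(apply_knockout(x, b, bad), "NotAVariable")
})

test_that("experiment specifications match the published driver groups", {
  expect_setequal(experiment_spec("boundary")$held_variables,
                  c("SO_nitrate", "SO_ammonia", "SO_phyt", "SO_detritus",
                    "D_nitrate", "D_ammonia", "D_phyt", "D_detritus",
                    "SI_nitrate", "SI_ammonia", "SI_phyt", "SI_detritus"))
  expect_setequal(experiment_spec("flows")$held_variables,
                  c("SO_OceanIN", "D_OceanIN", "SI_OceanIN", "SI_OceanOUT",
                    "SO_SI_flow"))
  expect_identical(experiment_spec("light")$held_variables, "Slight")
  expect_setequal(experiment_spec("temperature")$held_variables,
                  c("SO_temp", "D_temp", "SI_temp", "SO_AirTemp",
                    "SI_AirTemp"))
  at <- experiment_spec("attenuation")
  expect_identical(at$held_variables, experiment_spec("ice")$held_variables)
  expect_equal(at$param_overrides,
               c(light.k_ice = 0, light.k_snow = 0, light.albedo = 0))
  expect_error(experiment_spec("nope"), "unknown experiment")
})

test_that("driver files round-trip to full stored precision", {
  cfg <- scenario_config()
  d2 <- generate_decadal_drivers(cfg, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_drivers(d2, path)
  back <- read_drivers(path)
  expect_equal(unclass(back)[, ], unclass(d2)[, ], tolerance = 0)
  expect_identical(attr(back, "decade_label"), attr(d2, "decade_label"))
})

test_that("malformed driver files are rejected with informative errors", {
  cfg <- scenario_config()
  d0 <- generate_decadal_drivers(cfg, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_drivers(d0, path)
  tab <- utils::read.csv(path, comment.char = "#")
  # drop one month of one variable
  bad1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[!(tab$variable == "SO_temp" & tab$month == 5), ],
                   bad1, row.names = FALSE)
  expect_error(read_drivers(bad1), "SO_temp")
  # unknown extra variable is named in the error
  bad2 <- withr::local_tempfile(fileext = ".csv")
  extra <- data.frame(variable = "mystery_var", month = 1:12, value = 0)
  utils::write.csv(rbind(tab, extra), bad2, row.names = FALSE)
  expect_error(read_drivers(bad2), "mystery_var")
})

test_that("daily interpolation matches month midpoints and wraps the year", {
  cfg <- scenario_config()
  d0 <- generate_decadal_drivers(cfg, 0)
  at_mid <- drivers_at(d0, 15)  # midpoint of month 1
  expect_equal(at_mid[["SO_temp"]], unname(d0[1, "SO_temp"]))
  # halfway between months 1 and 2
  at_half <- drivers_at(d0, 30)
  expect_equal(at_half[["SO_temp"]],
               mean(d0[1:2, "SO_temp"]))
  # wrap: day 352.5 is halfway between month 12 and month 1
  at_wrap <- drivers_at(d0, 352.5)
  expect_equal(at_wrap[["SO_temp"]],
               unname(0.75 * d0[12, "SO_temp"] + 0.25 * d0[1, "SO_temp"]))
})

test_that("optional generator noise is seeded, bounded and off by default", {
  cfg_n <- scenario_config(seed = 42L, noise_sd = 0.05)
  a <- generate_decadal_drivers(cfg_n, 1)
  b <- generate_decadal_drivers(cfg_n, 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_decadal_drivers(
    scenario_config(seed = 43L, noise_sd = 0.05), 1)))
  frac <- a[, c("SO_IceFree", "SI_IceFree", "SO_IceCover", "SI_IceCover")]
  expect_true(all(frac >= 0 & frac <= 1))
  # the global RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_decadal_drivers(cfg_n, 1))
  expect_identical(runif(1), before)
})
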