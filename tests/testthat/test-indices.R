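p <- default_params()

test_that("nutrition shares classify uptake, detritivory and predation", {
  led <- chain_ledger(list("surface_nitrate|surface_phyt" = 10,
                           "surface_phyt|omni_zooplankton" = 5,
                           "surface_detritus|benthos_sd" = 5))
  sh <- nutrition_shares(led)
  expect_equal(unname(sh), c(50, 25, 25))
  expect_equal(sum(sh), 100)
  # producer-only ledger is pure primary production
  led2 <- chain_ledger(list("surface_nitrate|surface_phyt" = 3))
  expect_equal(nutrition_shares(led2)[["primary_production"]], 100)
  # empty ledger flagged undefined
  led0 <- make_ledger(matrix(0, 2, 2, dimnames = list(
    c("surface_phyt", "omni_zooplankton"),
    c("surface_phyt", "omni_zooplankton"))))
  expect_warning(sh0 <- nutrition_shares(led0), "undefined")
  expect_true(all(is.na(sh0)))
})

test_that("mass shares split mixed feeders by their inbound flow ratio", {
  led <- chain_ledger(list("surface_detritus|benthos_sd" = 3,
                           "deep_phyt|benthos_sd" = 1,
                           "surface_nitrate|surface_phyt" = 1))
  masses <- stats::setNames(numeric(35), compartment_names())
  masses["benthos_sd"] <- 40
  masses["surface_phyt"] <- 10
  sh <- mass_shares_by_mode(masses, led)
  # benthos: 30 to recycling, 10 to consumption; phyto 10 to production
  expect_equal(unname(sh), 100 * c(10, 30, 10) / 50)
  expect_equal(sum(sh), 100)
  # guild with mass but no inflow falls back to its category with a warning
  masses["carn_zooplankton"] <- 5
  expect_warning(sh2 <- mass_shares_by_mode(masses, led), "carn_zooplankton")
  expect_equal(sum(sh2), 100)
})

test_that("trophic levels solve the diet-weighted recursion exactly", {
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 4))
  tl <- trophic_levels(led)
  expect_equal(tl[["omni_zooplankton"]], 2)
  expect_equal(tl[["surface_phyt"]], 1)
  # 50% TL1 + 50% TL2 diet gives TL 2.5
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 4,
                           "surface_phyt|carn_zooplankton" = 2,
                           "omni_zooplankton|carn_zooplankton" = 2))
  expect_equal(trophic_levels(led)[["carn_zooplankton"]], 2.5)
})

test_that("trophic levels with feeding loops match the iterative oracle", {
  # loop between zooplankton and fish anchored by external phytoplankton
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 5,
                           "omni_zooplankton|carn_zooplankton" = 2,
                           "carn_zooplankton|omni_zooplankton" = 0.5))
  tl <- trophic_levels(led)
  tl_oracle <- oracle_trophic_levels(led)
  expect_equal(tl, tl_oracle, tolerance = 1e-10)
})

test_that("omnivory indices measure diet spread across trophic levels", {
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 4))
  expect_equal(omnivory_indices(led)[["omni_zooplankton"]], 0)
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 4,
                           "surface_phyt|carn_zooplankton" = 2,
                           "omni_zooplankton|carn_zooplankton" = 2))
  # diet 50% TL1 / 50% TL2: OI = 0.25
  expect_equal(omnivory_indices(led)[["carn_zooplankton"]], 0.25)
  # scaling all inflows leaves proportions, hence OI, unchanged
  led2 <- led; led2$T <- led2$T * 7.3
  expect_equal(omnivory_indices(led2), omnivory_indices(led))
})

test_that("ascendancy and capacity match hand evaluation and bounds", {
  # single flow: both sums vanish, ratio flagged undefined
  led1 <- chain_ledger(list("surface_phyt|omni_zooplankton" = 5))
  expect_warning(ac1 <- ascendancy_capacity(led1), "undefined|degenerate")
  expect_equal(ac1$A_internal, 0)
  expect_equal(ac1$C_internal, 0)
  expect_true(is.na(ac1$AC_ratio))
  # two disjoint unit flows: A = C = 2, ratio 1
  led2 <- chain_ledger(list("surface_phyt|omni_zooplankton" = 1,
                            "surface_detritus|benthos_sd" = 1))
  ac2 <- ascendancy_capacity(led2)
  expect_equal(ac2$A_internal, 2)
  expect_equal(ac2$C_internal, 2)
  expect_equal(ac2$AC_ratio, 1)
})

test_that("indirect-effect dominance matches hand algebra on chains", {
  # direct-only network has no indirect contribution
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 2))
  expect_equal(indirect_effects_dominance(led), 0)
  # unit chain a -> b -> c: one length-2 path over two direct links
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 1,
                           "omni_zooplankton|carn_zooplankton" = 1))
  expect_equal(indirect_effects_dominance(led), 0.5)
})

test_that("index kernels agree with brute-force oracles on random ledgers", {
  for (seed in 1:200) {
    led <- random_ledger(seed)
    expect_equal(trophic_levels(led), oracle_trophic_levels(led),
                 tolerance = 1e-9, info = paste("seed", seed))
    expect_equal(indirect_effects_dominance(led),
                 oracle_indirect_dominance(led),
                 tolerance = 1e-9, info = paste("seed", seed))
    ac <- ascendancy_capacity(led)
    orc <- oracle_ascendancy(led)
    expect_equal(ac$A_internal, orc$A, tolerance = 1e-9)
    expect_equal(ac$C_internal, orc$C, tolerance = 1e-9)
    expect_lte(ac$A_internal, ac$C_internal + 1e-12)
    expect_gte(ac$A_internal, -1e-12)
  }
})

test_that("indices are invariant under uniform flow scaling", {
  led <- random_ledger(42)
  led2 <- led
  led2$T <- led2$T * 3.7
  led2$imports <- led2$imports * 3.7
  expect_equal(trophic_levels(led2), trophic_levels(led))
  expect_equal(omnivory_indices(led2), omnivory_indices(led))
  expect_equal(indirect_effects_dominance(led2),
               indirect_effects_dominance(led))
  ac <- ascendancy_capacity(led)
  ac2 <- ascendancy_capacity(led2)
  expect_equal(ac2$AC_ratio, ac$AC_ratio)
  expect_equal(ac2$A_internal, 3.7 * ac$A_internal)
  expect_equal(ac2$C_internal, 3.7 * ac$C_internal)
  expect_equal(nutrition_shares(led2), nutrition_shares(led))
  expect_equal(f_ratio(led2), f_ratio(led))
})

test_that("F-ratio reflects the nitrate share of producer uptake", {
  led <- chain_ledger(list("surface_nitrate|surface_phyt" = 19,
                           "surface_ammonia|surface_phyt" = 1))
  expect_equal(f_ratio(led), 0.95)
  led <- chain_ledger(list("surface_nitrate|surface_phyt" = 2,
                           "surface_ammonia|surface_phyt" = 2))
  expect_equal(f_ratio(led), 0.5)
  led <- chain_ledger(list("surface_nitrate|surface_phyt" = 2))
  expect_equal(f_ratio(led), 1)
  led0 <- chain_ledger(list("surface_phyt|omni_zooplankton" = 1))
  expect_warning(expect_true(is.na(f_ratio(led0))), "undefined")
})

test_that("production metrics follow the assimilation budget", {
  # single consumer with intake 10, assimilation 0.7, excretion 0.2
  ps <- p
  ps$feeding$assim[["omni_zooplankton"]] <- 0.7
  ps$feeding$excr[["omni_zooplankton"]] <- 0.2
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 10))
  pm <- production_metrics(led, ps)
  expect_equal(pm[["secondary_production"]], 10 * 0.7 * (1 - 0.2))
  # no consumers: zero secondary production
  led2 <- chain_ledger(list("surface_nitrate|surface_phyt" = 5))
  expect_equal(production_metrics(led2, p)[["secondary_production"]], 0)
  # uptake balanced by producer losses gives zero npp
  led3 <- chain_ledger(list("surface_nitrate|surface_phyt" = 5,
                            "surface_phyt|omni_zooplankton" = 5))
  expect_equal(production_metrics(led3, p)[["npp"]], 0)
})

test_that("summary indices assemble mass-weighted means", {
  led <- chain_ledger(list("surface_phyt|omni_zooplankton" = 1,
                           "omni_zooplankton|pinnipeds" = 1,
                           "omni_zooplankton|cetaceans" = 1))
  masses <- stats::setNames(numeric(35), compartment_names())
  masses[c("pinnipeds", "cetaceans")] <- 1
  masses["omni_zooplankton"] <- 2
  ix <- suppressWarnings(summary_indices(led, masses, p))
  # both predators eat TL-2 zooplankton: mean top-predator TL is 3
  expect_equal(ix$mean_TL_top_predators, 3)
  # equal masses: weighted mean equals the arithmetic mean
  tl <- trophic_levels(led)
  expect_equal(ix$mean_TL_top_predators,
               mean(tl[c("pinnipeds", "cetaceans")]))
  # single effective consumer mass dominates the OI mean
  oi <- omnivory_indices(led)
  w <- masses[setdiff(living_names(), producer_names())]
  expect_equal(ix$mean_OI_consumers,
               sum(w * oi[names(w)]) / sum(w))
})

test_that("mass-weighted top-predator mean reproduces a hand average", {
  # two top predators with equal mass at TL 3.9 and 4.2 average to 4.05
  tl <- c(3.9, 4.2)
  w <- c(1, 1)
  expect_equal(sum(w * tl) / sum(w), 4.05)
})

test_that("index reports round-trip through the key/value table", {
  led <- chain_ledger(list("surface_nitrate|surface_phyt" = 10,
                           "surface_phyt|omni_zooplankton" = 5,
                           "surface_detritus|benthos_sd" = 5))
  masses <- stats::setNames(numeric(35), compartment_names())
  masses[c("surface_phyt", "omni_zooplankton", "benthos_sd")] <- c(5, 2, 3)
  ix <- suppressWarnings(summary_indices(led, masses, p))
  path <- withr::local_tempfile(fileext = ".csv")
  write_indices(ix, path)
  back <- utils::read.csv(path)
  expect_equal(back$value[back$key == "share_flow.primary_production"], 50)
  expect_equal(back$value[back$key == "TL.omni_zooplankton"], 2)
})
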