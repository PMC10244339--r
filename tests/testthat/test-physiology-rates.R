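test_that("growth rate is the surface-area change per day", {
  expect_equal(growth_rate(19.6, 25.2, 14), 0.4)
  expect_equal(growth_rate(19.6, 19.6, 14), 0)
  expect_equal(growth_rate(20.0, 17.2, 14), -0.2)
  expect_error(growth_rate(19.6, 25.2, 0), "> 0")
})

test_that("DOC flux normalises to volume, time and dry biomass", {
  expect_equal(doc_flux(100, 110, 0.25, 24, 0.5), 10 * 0.25 / (0.5 * 24))
  expect_equal(doc_flux(100, 100, 0.25, 24, 0.5), 0)
  # antisymmetry under endpoint swap
  expect_equal(doc_flux(110, 100, 0.25, 24, 0.5),
               -doc_flux(100, 110, 0.25, 24, 0.5))
  # unit-consistent rescaling: doubling volume, halving the
  # concentration change leaves the flux fixed
  expect_equal(doc_flux(100, 105, 0.5, 24, 0.5),
               doc_flux(100, 110, 0.25, 24, 0.5))
  expect_error(doc_flux(100, 110, 0, 24, 0.5), "> 0")
})

test_that("O2 flux signs follow the light/dark assay conventions", {
  expect_equal(o2_flux(200, 260, 0.25, 3, 1.0, "light"), 5.0)
  expect_equal(o2_flux(260, 200, 0.25, 12, 1.0, "dark"), 1.25)
  expect_equal(o2_flux(200, 200, 0.25, 3, 1.0, "light"), 0)
  expect_equal(o2_flux(200, 200, 0.25, 12, 1.0, "dark"), 0)
  # same endpoints, opposite phase: sign flips
  expect_equal(o2_flux(200, 260, 0.25, 3, 1.0, "light"),
               -o2_flux(200, 260, 0.25, 3, 1.0, "dark"))
  expect_error(o2_flux(200, 260, 0.25, 3, 1.0, "twilight"))
})

test_that("soluble nitrate standardises the two extractions to wet weight", {
  expect_equal(soluble_nitrate(10, 2, 0.2), 1.2)
  expect_equal(soluble_nitrate(0, 0, 0.2), 0)
  expect_equal(soluble_nitrate(5, 5, 0.1, 0.02), 2.0)
  expect_error(soluble_nitrate(10, 2, 0), "> 0")
})

test_that("Fv/Fm is bounded and validates the fluorescence pair", {
  expect_equal(fv_fm(0.2, 0.8), 0.75)
  expect_equal(fv_fm(0.37, 0.37), 0)
  expect_equal(fv_fm(0, 1), 1)
  expect_error(fv_fm(0.9, 0.8), "f_o")
  expect_error(fv_fm(0.2, 0), "> 0")
})

test_that("C:N uses atomic weights and is scale invariant", {
  expect_equal(cn_atomic_ratio(30, 3), (30 / 12.011) / (3 / 14.007),
               tolerance = 1e-12)
  expect_equal(round(cn_atomic_ratio(30, 3), 2), 11.66)
  expect_equal(cn_atomic_ratio(5, 5), 14.007 / 12.011)
  expect_equal(cn_atomic_ratio(30, 3), cn_atomic_ratio(60, 6))
  expect_error(cn_atomic_ratio(30, 0), "> 0")
})

test_that("pigment estimate is linear in the absorbances", {
  zero <- list(dmso = c("665" = 0, "631" = 0, "582" = 0),
               acetone = c("664" = 0, "631" = 0, "581" = 0))
  expect_equal(total_chlorophyll(zero, tissue_mass = 0.1), 0)
  one <- list(dmso = c("665" = 0.4, "631" = 0.2, "582" = 0.05),
              acetone = c("664" = 0.3, "631" = 0.1, "581" = 0.02))
  two <- lapply(one, function(v) 2 * v)
  expect_equal(total_chlorophyll(two, tissue_mass = 0.1),
               2 * total_chlorophyll(one, tissue_mass = 0.1))
})

test_that("a configured unit-coefficient matrix matches the hand sum", {
  unit_coef <- list(dmso = list(chl_a = c("665" = 1),
                                chl_c = c("631" = 1, "582" = 1)))
  abs1 <- list(dmso = c("665" = 1, "631" = 1, "582" = 1))
  # hand computation: (1 + 1 + 1) g/L * 0.004 L * 1000 mg/g / 0.1 g
  expect_equal(
    total_chlorophyll(abs1, extract_volumes = c(dmso = 0.004),
                      tissue_mass = 0.1, coefficients = unit_coef),
    3 * 0.004 * 1000 / 0.1)
  expect_error(
    total_chlorophyll(list(dmso = c("665" = 1)),
                      extract_volumes = c(dmso = 0.004),
                      tissue_mass = 0.1, coefficients = unit_coef),
    "missing")
})

test_that("replicate_rates recovers drawn rates and propagates NA", {
  reps <- generate_replicates(synthetic_config(seed = 11))
  rates <- replicate_rates(reps)
  expect_equal(nrow(rates), nrow(reps))
  live <- !reps$is_control
  expect_equal(rates$growth[live],
               (reps$sa_final_cm2[live] - reps$sa_initial_cm2[live]) / 14)
  # controls carry no tissue metrics
  expect_true(all(is.na(rates$growth[!live])))
  # a missing raw field blanks only its own metric
  reps$f_m[3] <- NA
  rates2 <- replicate_rates(reps)
  expect_true(is.na(rates2$fv_fm[3]))
  expect_false(is.na(rates2$growth[3]))
})

test_that("replicate validation aggregates row numbers", {
  reps <- generate_replicates(synthetic_config(seed = 11))
  reps$wet_mass_g[5] <- -1
  reps$dry_mass_g[9] <- 0
  err <- tryCatch(validate_replicates(reps), error = function(e)
    conditionMessage(e))
  expect_match(err, "wet_mass_g")
  expect_match(err, "rows 5")
  expect_match(err, "rows 9")
})
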