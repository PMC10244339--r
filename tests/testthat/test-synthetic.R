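test_that("design arithmetic: 7 levels x 6 replicates + 4 controls", {
  reps <- generate_replicates(synthetic_config(seed = 3))
  expect_equal(nrow(reps), 7 * 6 + 4)
  expect_equal(sum(reps$is_control), 4)
  expect_equal(length(unique(reps$treatment_fe_prime[!reps$is_control])),
               7)
  # controls split between the lowest and highest level
  ctrl_levels <- reps$treatment_fe_prime[reps$is_control]
  expect_setequal(unique(ctrl_levels),
                  range(reps$treatment_fe_prime))
})

test_that("same seed gives identical tables, different seeds differ", {
  cfg <- synthetic_config(seed = 99)
  expect_identical(generate_replicates(cfg), generate_replicates(cfg))
  other <- generate_replicates(synthetic_config(seed = 100))
  expect_false(identical(generate_replicates(cfg), other))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_replicates(synthetic_config(seed = 1)))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero noise collapses growth onto the Michaelis-Menten mean", {
  cfg <- synthetic_config(growth_cv = 0, seed = 5)
  reps <- generate_replicates(cfg)
  rates <- replicate_rates(reps)
  live <- rates[!rates$is_control, ]
  mm <- cfg$growth_vmax * live$treatment_fe_prime /
    (cfg$growth_km + live$treatment_fe_prime)
  expect_equal(live$growth, mm, tolerance = 1e-12)
})

test_that("DOC fluxes respect the threshold structure row by row", {
  for (seed in c(2, 17, 31)) {
    cfg <- synthetic_config(seed = seed)
    rates <- replicate_rates(generate_replicates(cfg))
    live <- rates[!rates$is_control, ]
    limited <- live$treatment_fe_prime <= cfg$limitation_threshold
    expect_true(all(live$doc_flux[limited] >=
                      cfg$doc_limited_range[1] - 1e-9))
    expect_true(all(live$doc_flux[limited] <=
                      cfg$doc_limited_range[2] + 1e-9))
    expect_true(all(live$doc_flux[!limited] >=
                      cfg$doc_replete_range[1] - 1e-9))
    expect_true(all(live$doc_flux[!limited] <=
                      cfg$doc_replete_range[2] + 1e-9))
  }
})

test_that("replete treatments show the elevated physiological profile", {
  cfg <- synthetic_config(seed = 13)
  rates <- replicate_rates(generate_replicates(cfg))
  live <- rates[!rates$is_control, ]
  limited <- live$treatment_fe_prime <= cfg$limitation_threshold
  for (metric in c("net_photosynthesis", "respiration", "cn_ratio",
                   "total_chl", "fv_fm", "soluble_no3")) {
    expect_gt(mean(live[[metric]][!limited]),
              mean(live[[metric]][limited]))
  }
})

test_that("configuration round-trips through its file form losslessly", {
  cfg <- synthetic_config(seed = 2024, growth_cv = 0.31,
                          growth_km = 4.27e-9)
  path <- tempfile(fileext = ".json")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2, cfg)
  expect_identical(generate_replicates(cfg2), generate_replicates(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(replicates_per_level = 0), ">= 1")
  expect_error(synthetic_config(doc_limited_range = c(2, 1)), "ordered")
  expect_error(synthetic_config(mortality_prob_limited = 1.5),
               "\\[0, 1\\]")
  expect_error(recover_parameters(synthetic_config(), 0), ">= 1")
})

test_that("zero-noise simulations recover the parameters without bias", {
  cfg <- synthetic_config(growth_cv = 0, seed = 8)
  rec <- recover_parameters(cfg, n_sims = 3)
  expect_equal(unname(rec$bias), c(0, 0), tolerance = 1e-6)
})

test_that("more replicates do not worsen the spread of Km estimates", {
  base <- synthetic_config(growth_cv = 0.2, seed = 300)
  wide <- synthetic_config(growth_cv = 0.2, seed = 300,
                           replicates_per_level = 12)
  rec6 <- recover_parameters(base, n_sims = 40)
  rec12 <- recover_parameters(wide, n_sims = 40)
  expect_lte(rec12$iqr["km"], rec6$iqr["km"])
})
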