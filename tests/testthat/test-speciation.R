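test_that("K'(light) sums the dark and irradiance-scaled photo terms", {
  expect_equal(conditional_k_light(std_constants()), 1.807e-7,
               tolerance = 0.005)
  expect_equal(conditional_k_light(fe_edta_constants(4.98e-8, 8.01e-7, 0)),
               4.98e-8)
  expect_equal(conditional_k_light(fe_edta_constants(0, 8.01e-7, 0.5)),
               4.005e-7)
  expect_error(fe_edta_constants(-1e-8, 8.01e-7, 0.1), "non-negative")
  expect_error(fe_edta_constants(4.98e-8, 8.01e-7, 1.2), "\\[0, 1\\]")
})

test_that("buffer model reproduces the printed treatment Fe' values", {
  res <- treatment_speciation(std_additions, std_medium(),
                              std_constants())
  # six upper treatments within 1% of the printed values
  expect_equal(res$fe_prime[-1] * 1e9, printed_fe_prime_nM[-1],
               tolerance = 0.01)
  # background-only treatment computes ~0.013 nM, printed as 0.01 order
  expect_lt(res$fe_prime[1] * 1e9, 0.02)
  expect_gt(res$fe_prime[1] * 1e9, 0.005)
  # Fe':Fe(tot) ratio at the highest treatment
  expect_rel(res$ratio[7], 2.99e-3, 0.01)
})

test_that("speciation handles zero iron and exhausted buffer", {
  r0 <- fe_prime(0, std_medium(), std_constants())
  expect_equal(r0$fe_prime, 0)
  expect_false(r0$exceeds_solubility)
  expect_error(fe_prime(2e-4, std_medium(), std_constants()),
               "exhausted")
  expect_error(fe_prime(-1e-9, std_medium(), std_constants()), ">= 0")
})

test_that("solubility partition preserves the nominal Fe' label", {
  res <- treatment_speciation(std_additions, std_medium(),
                              std_constants())
  expect_equal(res$fe_prime, res$ratio * res$fe_total)
  expect_true(all(res$fe_prime_effective <= res$fe_prime))
  expect_true(all(res$fe_prime_effective[res$exceeds_solubility] ==
                    fe_prime_solubility_limit))
  expect_true(all(res$fe_colloidal >= 0))
  expect_equal(res$fe_colloidal,
               res$fe_prime - res$fe_prime_effective)
  # only the background-only treatment stays below the 700 pM limit
  expect_equal(res$exceeds_solubility, c(FALSE, rep(TRUE, 6)))
})

test_that("closed form agrees with the iterative oracle at a mid treatment", {
  m <- std_medium(); k <- std_constants()
  ft <- 2.5e-6 + 7.25e-9
  closed <- fe_prime(ft, m, k)$fe_prime
  oracle <- fe_prime_mass_balance(ft, m, k, tol = 1e-12)
  expect_rel(closed, oracle, 0.01)
})

test_that("fe_prime and the ratio increase strictly with total iron", {
  m <- std_medium(); k <- std_constants()
  ft <- seq(1e-9, 9e-5, length.out = 50)
  res <- fe_prime(ft, m, k)
  expect_true(all(diff(res$fe_prime) > 0))
  expect_true(all(diff(res$ratio) > 0))
})

test_that("dilute limit of the ratio is K'(light)/EDTA_total", {
  m <- std_medium(); k <- std_constants()
  r <- fe_prime(1e-15, m, k)
  expect_rel(r$ratio, conditional_k_light(k) / m$edta_total, 1e-9)
})

test_that("design mode inverts the forward map exactly", {
  m <- std_medium(); k <- std_constants()
  # printed pairing: 45.2 nM Fe' needs ~20 uM total iron
  expect_rel(invert_fe_total(45.2e-9, m, k), 20e-6, 0.005)
  x <- c(0.1, 1, 10, 100) * 1e-9
  expect_rel(fe_prime(invert_fe_total(x, m, k), m, k)$fe_prime, x, 1e-9)
  # target = K'(light) puts total iron at half the buffer, matching an
  # independent bisection on the forward map
  target <- conditional_k_light(k)
  fe_t <- invert_fe_total(target, m, k)
  expect_rel(fe_t, m$edta_total / 2, 1e-12)
  expect_rel(fe_t, invert_by_bisection(target, m, k), 1e-9)
  expect_error(invert_fe_total(2e-4, m, k), "exhausted")
  expect_error(invert_fe_total(0, m, k), "> 0")
})

test_that("open-ocean Fe' approximation hits its anchors and is monotone", {
  expect_rel(ocean_dfe_to_fe_prime(0.1e-9) * 1e12, 0.11, 1e-9)
  expect_rel(ocean_dfe_to_fe_prime(0.6e-9) * 1e12, 1.49, 1e-9)
  expect_equal(as.numeric(ocean_dfe_to_fe_prime(0)), 0)
  dfe <- seq(0.05e-9, 1e-9, length.out = 20)
  expect_true(all(diff(as.numeric(ocean_dfe_to_fe_prime(dfe))) > 0))
  expect_true(isTRUE(attr(ocean_dfe_to_fe_prime(0.3e-9), "approximate")))
  expect_error(ocean_dfe_to_fe_prime(-1e-10), ">= 0")
  expect_warning(ocean_dfe_to_fe_prime(2e-9), "window")
})

test_that("concentration parsing converts suffixed values", {
  expect_equal(parse_conc(c("100uM", "45.2nM", "700pM", "1e-7M")),
               c(1e-4, 45.2e-9, 700e-12, 1e-7))
  expect_equal(parse_conc("7.25 nM"), 7.25e-9)
  expect_equal(parse_conc(3.5e-8), 3.5e-8)
  expect_error(parse_conc("ten nM"), "cannot parse")
  expect_error(parse_conc("5 kM"), "unknown")
})
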