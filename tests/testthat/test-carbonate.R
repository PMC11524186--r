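test_that("equilibrium constants match the frozen fixture table", {
  fix <- read.csv(system.file("extdata", "carbonate_constants.csv",
                              package = "lakecarb"))
  kc <- equilibrium_constants(fix$temp_c)
  expect_equal(-log10(kc$k1), fix$pk1, tolerance = 1e-6)
  expect_equal(-log10(kc$k2), fix$pk2, tolerance = 1e-6)
  expect_equal(-log10(kc$kw), fix$pkw, tolerance = 1e-6)
  expect_equal(-log10(kc$kh), fix$pkh, tolerance = 1e-6)
  expect_equal(-log10(kc$ksp), fix$pksp, tolerance = 1e-6)
})

test_that("constants behave physically across the temperature range", {
  kc25 <- equilibrium_constants(25)
  # first and second dissociation about four orders of magnitude apart
  expect_gt(log10(kc25$k1 / kc25$k2), 3.5)
  expect_lt(log10(kc25$k1 / kc25$k2), 4.5)
  # CO2 more soluble in cold water
  expect_gt(equilibrium_constants(5)$kh, kc25$kh)
  # neutral pure water at 25 degC
  expect_equal(solve_speciation(1e-6, 0, 25)$ph, 7.0, tolerance = 0.01)
  for (k in names(kc25)) expect_true(all(equilibrium_constants(0:30)[[k]] > 0))
  expect_error(equilibrium_constants(45), "range")
  expect_error(equilibrium_constants(-10), "range")
})

test_that("ionic strength sums charge-weighted ions plus the background", {
  expect_identical(ionic_strength(0, 0, 0, background = 0), 0)
  expect_equal(ionic_strength(1000, 0, 0, background = 0), 2e-3)
  # Geneva-like parcel, hand evaluation of 0.5 * sum(c z^2) + background
  hand <- 0.5e-6 * (4 * 1100 + 1650 + 4 * 5) + 1e-3
  expect_equal(ionic_strength(1100, 1650, 5), hand)
})

test_that("Davies coefficients have the infinite-dilution and z^2 limits", {
  expect_identical(activity_coefficient(1L, 0), 1)
  expect_equal(activity_coefficient(2L, 0.01), activity_coefficient(-2L, 0.01))
  # hand evaluation at I = 1e-2, z = 1
  hand <- 10^(-0.509 * (sqrt(0.01) / (1 + sqrt(0.01)) - 0.3 * 0.01))
  expect_equal(activity_coefficient(1L, 0.01), hand)
  expect_lt(activity_coefficient(2L, 0.01), activity_coefficient(1L, 0.01))
  expect_error(activity_coefficient(1L, -1), "ionic strength")
})

test_that("solved speciation closes carbon and alkalinity balances", {
  p <- random_parcels(200, seed = 11)
  sp <- solve_speciation(p$dic, p$tac, p$temp, p$ca)
  # carbon closure
  expect_equal(sp$co2aq + sp$hco3 + sp$co3, p$dic, tolerance = 1e-9)
  expect_true(all(sp$co2aq >= 0 & sp$hco3 >= 0 & sp$co3 >= 0))
  expect_true(all(sp$ph > 2 & sp$ph < 13))
  # alkalinity closure at the returned pH
  g1 <- activity_coefficient(1L, sp$ionic_strength)
  kw <- equilibrium_constants(p$temp)$kw
  h <- 10^-sp$ph
  alk <- sp$hco3 + 2 * sp$co3 + (kw / (h * g1)) * 1e6 - (h / g1) * 1e6
  expect_equal(alk, p$tac, tolerance = 1e-6)
})

test_that("solver pH agrees with the brute-force grid oracle", {
  p <- random_parcels(100, seed = 3)
  sp <- solve_speciation(p$dic, p$tac, p$temp, p$ca)
  orc <- mapply(oracle_ph, p$dic, p$tac, p$temp, p$ca)
  expect_lt(max(abs(sp$ph - orc)), 2e-4)
  # frozen single case: cold DIC-rich winter water
  expect_equal(solve_speciation(1800, 1700, 6, ca = 1100)$ph,
               oracle_ph(1800, 1700, 6, ca = 1100), tolerance = 2e-4)
})

test_that("pH is monotone in alkalinity and pCO2 monotone in DIC", {
  tacs <- seq(1400, 2000, by = 50)
  ph <- solve_speciation(1800, tacs, 10, ca = 1000)$ph
  expect_true(all(diff(ph) > 0))
  dics <- seq(1400, 2600, by = 100)
  pco2 <- solve_speciation(dics, 1700, 10, ca = 1000)$pco2
  expect_true(all(diff(pco2) > 0))
})

test_that("DIC recovered from (pH, TAC) round-trips the solver", {
  p <- random_parcels(50, seed = 5)
  sp <- solve_speciation(p$dic, p$tac, p$temp, p$ca)
  back <- dic_from_ph_tac(sp$ph, p$tac, p$temp, p$ca)
  expect_equal(back$dic, p$dic, tolerance = 1e-6)
})

test_that("chemically infeasible alkalinity raises an informative error", {
  expect_error(solve_speciation(100, 5000, 10), "infeasible")
  expect_error(solve_speciation(-5, 100, 10), "dic")
})

test_that("calcite saturation responds to calcium and season", {
  expect_identical(omega_calcite(0, 10, 15, 4e-3), 0)
  # linear in calcium activity at fixed speciation
  expect_equal(omega_calcite(2000, 10, 15, 4e-3),
               2 * omega_calcite(1000, 10, 15, 4e-3))
  # warm productive surface water is supersaturated, cold winter water not
  summer <- solve_speciation(1430, 1530, 22, ca = 1000)
  winter <- solve_speciation(1800, 1740, 6, ca = 1000)
  expect_gt(summer$omega_calcite, 1.5)
  expect_lt(winter$omega_calcite, 1.5)
  # and the winter parcel sits near 300% CO2 saturation
  expect_gt(winter$omega_co2, 2)
})
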