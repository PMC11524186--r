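test_that("precipitation switches on strictly above the trigger", {
  prm <- calcite_params()
  expect_identical(precipitation_rate(c(0, 1.4, 1.5), prm), c(0, 0, 0))
  expect_identical(precipitation_rate(1.5 + 1e-12, prm), 2.5)
  expect_identical(precipitation_rate(c(1.6, 8), prm), c(2.5, 2.5))
  expect_error(precipitation_rate(-0.1, prm), "omega")
  expect_error(calcite_params(omega_threshold = 0.9))
})

test_that("precipitation applies exact 1:2:1 reaction stoichiometry", {
  out <- apply_precipitation(dic = 1800, tac = 1700, ca = 1000,
                             particulate = 0, rate = 2.5, dt = 1)
  expect_identical(out$dic, 1800 - 2.5)
  expect_identical(out$tac, 1700 - 5.0)
  expect_identical(out$ca, 1000 - 2.5)
  expect_identical(out$particulate, 2.5)
  # zero rate is the identity
  id <- apply_precipitation(1800, 1700, 1000, 3, rate = 0)
  expect_identical(id[c("dic", "tac", "ca", "particulate")],
                   list(dic = 1800, tac = 1700, ca = 1000, particulate = 3))
  expect_error(apply_precipitation(1, 1, 1, 0, 1, dt = -1), "dt")
})

test_that("the limiter clips precipitation at the scarcest reactant", {
  # alkalinity-limited: tac/2 = 1 caps the conversion
  out <- apply_precipitation(dic = 10, tac = 2, ca = 10, particulate = 0,
                             rate = 2.5, dt = 1)
  expect_identical(out$precipitated, 1)
  expect_identical(out$tac, 0)
  # calcium-limited
  out <- apply_precipitation(10, 100, 0.5, 0, 2.5, 1)
  expect_identical(out$precipitated, 0.5)
  expect_true(all(unlist(out[c("dic", "tac", "ca")]) >= 0))
})

test_that("ten closed-box steps keep the cumulative 2:1 alkalinity ledger", {
  dic <- 1800; tac <- 1700; ca <- 1000; part <- 0
  for (i in 1:10) {
    out <- apply_precipitation(dic, tac, ca, part, rate = 2.5, dt = 1)
    dic <- out$dic; tac <- out$tac; ca <- out$ca; part <- out$particulate
  }
  expect_identical(1700 - tac, 2 * part)
  expect_identical(1000 - ca, part)
  expect_identical(1800 - dic, part)
})

test_that("settling conserves calcite and deposits through the bottom", {
  g <- flat_grid(n = 25, dz = 2, area = 1)
  part <- rep(1, g$n)
  sed <- numeric(g$n)
  # zero velocity is the identity
  out0 <- settle_calcite(part, sed, g, velocity = 0)
  expect_identical(out0$particulate, part)
  # uniform column, 2 m/day for one day: bottom interface passes 2 mmol m^-2
  out <- settle_calcite(part, sed, g, velocity = 2, dt = 1)
  areal <- sediment_areal(out$sediment, g)
  expect_equal(areal[g$n], 2)
  expect_true(all(is.na(areal[-g$n])))   # flat walls: no shelves above bottom
  # conservation to round-off, including on a tapered basin
  tg <- lake_grid(dz = 2, max_depth = 100, surface_area = 1e6,
                  hyps_max_depth = 104)
  tp <- runif(tg$n, 0, 3)
  before <- sum(tp * tg$volume)
  st <- settle_calcite(tp, numeric(tg$n), tg, velocity = 1.5, dt = 1)
  after <- sum(st$particulate * tg$volume) + sum(st$sediment)
  expect_equal(after, before, tolerance = 1e-12)
  expect_error(settle_calcite(part, sed, g, velocity = 3, dt = 1), "CFL")
})

test_that("sediment redissolution returns calcite with reversed stoichiometry", {
  g <- flat_grid(n = 5, dz = 2, area = 1)
  sed <- c(numeric(4), 100)      # mmol on 1 m^2: 100 mmol m^-2 at the bottom
  out <- sediment_redissolution(sed, dic = rep(0, 5), tac = rep(0, 5),
                                ca = rep(0, 5), g, timescale = 10, dt = 1)
  expect_equal(out$sediment[5], 90)
  expect_equal(out$tac[5], 10)    # 2 * 10 mmol / (2 m * 1 m^2)
  expect_equal(out$dic[5], 5)
  expect_equal(out$ca[5], 5)
  # empty pool is the identity
  out0 <- sediment_redissolution(numeric(5), rep(1, 5), rep(1, 5), rep(1, 5),
                                 g, timescale = 10)
  expect_identical(out0$sediment, numeric(5))
  expect_identical(out0$tac, rep(1, 5))
})

test_that("redissolution is throttled by the overlying saturation state", {
  g <- flat_grid(n = 2, dz = 2, area = 1)
  sed <- c(0, 100)
  base <- sediment_redissolution(sed, c(0, 0), c(0, 0), c(0, 0), g, 10, 1)
  half <- sediment_redissolution(sed, c(0, 0), c(0, 0), c(0, 0), g, 10, 1,
                                 omega = c(1, 0.5))
  shut <- sediment_redissolution(sed, c(0, 0), c(0, 0), c(0, 0), g, 10, 1,
                                 omega = c(1, 1.2))
  expect_equal(base$dissolved[2], 10)
  expect_equal(half$dissolved[2], 5)
  expect_identical(shut$dissolved[2], 0)
})

test_that("the full calcite loop conserves alkalinity and calcium", {
  # precipitate, settle to the bottom, redissolve: whole-system TAC + 2*CaCO3
  # and Ca + CaCO3 are invariant throughout, and after full return the
  # dissolved pools recover their initial totals
  g <- flat_grid(n = 4, dz = 2, area = 1)
  dic <- rep(1800, 4); tac <- rep(1700, 4); ca <- rep(1000, 4)
  part <- numeric(4); sed <- numeric(4)
  tot_tac <- function() sum(tac * g$volume) + 2 * (sum(part * g$volume) + sum(sed))
  tot_ca <- function() sum(ca * g$volume) + sum(part * g$volume) + sum(sed)
  tac0 <- tot_tac(); ca0 <- tot_ca()
  for (d in 1:120) {
    ap <- apply_precipitation(dic, tac, ca, part,
                              rate = c(2.5, 0, 0, 0) * (d <= 5), dt = 1)
    dic <- ap$dic; tac <- ap$tac; ca <- ap$ca; part <- ap$particulate
    st <- settle_calcite(part, sed, g, velocity = 1, dt = 1)
    part <- st$particulate; sed <- st$sediment
    rd <- sediment_redissolution(sed, dic, tac, ca, g, timescale = 5, dt = 1)
    dic <- rd$dic; tac <- rd$tac; ca <- rd$ca; sed <- rd$sediment
    expect_equal(tot_tac(), tac0, tolerance = 1e-12)
    expect_equal(tot_ca(), ca0, tolerance = 1e-12)
  }
  # long after precipitation stopped, everything has redissolved
  expect_lt(sum(part * g$volume) + sum(sed), 1e-6)
  expect_equal(sum(tac * g$volume), 1700 * sum(g$volume), tolerance = 1e-9)
})
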