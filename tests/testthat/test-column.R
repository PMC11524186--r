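test_that("implicit diffusion conserves inventories and creates no extrema", {
  g <- lake_grid(dz = 2, max_depth = 100, surface_area = 1e6,
                 hyps_max_depth = 104)
  kz <- rep(5, g$n + 1)
  # a constant profile is untouched
  expect_equal(diffuse(rep(3, g$n), kz, g), rep(3, g$n))
  # random profile: inventory conserved, bounds respected
  set.seed(1)
  c0 <- runif(g$n, 0, 10)
  c1 <- diffuse(c0, kz, g, dt = 1)
  expect_equal(sum(c1 * g$volume), sum(c0 * g$volume), tolerance = 1e-12)
  expect_true(all(c1 <= max(c0) + 1e-12 & c1 >= min(c0) - 1e-12))
  expect_error(diffuse(c0, rep(-1, g$n + 1), g), "diffusivity")
})

test_that("a step profile homogenises at the volume-weighted mean", {
  g <- lake_grid(dz = 2, max_depth = 40, surface_area = 1e6,
                 hyps_max_depth = 50)
  c0 <- c(rep(10, 10), rep(2, 10))
  c1 <- c0
  for (i in 1:500) c1 <- diffuse(c1, rep(100, g$n + 1), g, dt = 1)
  expect_equal(c1, rep(sum(c0 * g$volume) / sum(g$volume), g$n),
               tolerance = 1e-9)
})

test_that("diffusion matches the closed-form Gaussian on a uniform column", {
  g <- flat_grid(n = 100, dz = 1)
  k <- 1                                  # m^2 day^-1
  gauss <- function(z, t) exp(-(z - 50)^2 / (4 * k * t)) / sqrt(4 * pi * k * t)
  conc <- gauss(g$mids, 10)
  for (i in 1:200) conc <- diffuse(conc, rep(k, g$n + 1), g, dt = 0.1)
  expect_lt(max(abs(conc - gauss(g$mids, 30))), 5e-4)
})

test_that("NEP moves DIC with a floor and reports the realised removal", {
  out <- apply_nep(rep(1800, 3), c(5, 0, -4), dt = 1)
  expect_equal(out$dic, c(1795, 1800, 1804))
  expect_equal(out$removed, c(5, 0, -4))
  # removal cannot draw DIC below the floor
  lim <- apply_nep(2, 5, dt = 1, floor = 1)
  expect_equal(lim$dic, 1)
  expect_equal(lim$removed, 1)
})

test_that("river exchange is volume-conserving and mass-consistent", {
  g <- flat_grid(n = 10, dz = 2)
  fields <- list(dic = rep(5, 10))
  riv <- list(discharge = 0, temp = 8, dic = 100)
  out <- river_exchange(fields, riv, rep(8, 10), g)
  expect_identical(out$fields$dic, fields$dic)
  # inflow at lake concentration leaves the total mass unchanged
  riv$discharge <- 1
  riv$dic <- 5
  out <- river_exchange(fields, riv, rep(8, 10), g, intrusion_range = c(3, 15))
  expect_equal(sum(out$fields$dic * g$volume), sum(fields$dic * g$volume),
               tolerance = 1e-12)
  expect_equal(unname(out$in_mass["dic"]), 5)
  expect_equal(unname(out$out_mass["dic"]), 5)
})

test_that("a flushed conservative tracer approaches the inflow concentration", {
  g <- flat_grid(n = 10, dz = 2)           # 20 m^3 of water on 1 m^2
  q <- 0.5                                 # residence time 40 days
  fields <- list(dic = rep(0, 10))
  for (d in 1:200) {
    out <- river_exchange(fields, list(discharge = q, temp = 8, dic = 100),
                          rep(8, 10), g, intrusion_range = c(3, 15))
    fields$dic <- diffuse(out$fields$dic, rep(1000, g$n + 1), g)
  }
  expect_equal(mean(fields$dic), 100 * (1 - exp(-200 / 40)), tolerance = 0.02)
})

test_that("a forcing-free muted column is invariant under stepping", {
  cfg <- small_config()
  cfg$calcite$enabled <- FALSE
  cfg <- validate_config(cfg)
  g <- do.call(lake_grid, cfg$grid)
  state <- list(temp = rep(10, g$n), dic = rep(1800, g$n),
                tac = rep(1700, g$n), ca = rep(1000, g$n),
                particulate = numeric(g$n), sediment = numeric(g$n),
                day = 0L)
  pco2 <- solve_speciation(1800, 1700, 10, 1000)$pco2
  frc <- list(temp = state$temp, kz = numeric(g$n + 1), nep = numeric(g$n),
              river = list(discharge = 0, temp = 10), atm_pco2 = pco2)
  s <- state
  for (i in 1:5) s <- step_day(s, frc, cfg, g)$state
  for (f in c("dic", "tac", "ca")) expect_equal(s[[f]], state[[f]], tolerance = 1e-9)
  expect_identical(s$particulate, numeric(g$n))
})

test_that("closed-column precipitation drops alkalinity by twice the calcite", {
  cfg <- small_config()
  cfg <- validate_config(cfg)
  g <- do.call(lake_grid, cfg$grid)
  # warm, supersaturated everywhere: CP runs at the constant rate
  state <- list(temp = rep(22, g$n), dic = rep(1430, g$n),
                tac = rep(1530, g$n), ca = rep(1000, g$n),
                particulate = numeric(g$n), sediment = numeric(g$n),
                day = 0L)
  pco2 <- solve_speciation(1430, 1530, 22, 1000)$pco2
  frc <- list(temp = state$temp, kz = numeric(g$n + 1), nep = numeric(g$n),
              river = list(discharge = 0, temp = 22), atm_pco2 = pco2)
  out <- step_day(state, frc, cfg, g)
  s <- out$state
  calcite_formed <- sum(out$diag$precip * g$volume)
  expect_gt(calcite_formed, 0)
  d_tac <- sum((state$tac - s$tac) * g$volume)
  expect_equal(d_tac, 2 * calcite_formed, tolerance = 1e-12)
  d_ca <- sum((state$ca - s$ca) * g$volume)
  expect_equal(d_ca, calcite_formed, tolerance = 1e-12)
})

test_that("multi-year runs close the carbon, alkalinity and calcium ledgers", {
  res <- run_simulation(validate_config(small_config(years = 2)))
  led <- carbon_ledger(res)
  expect_lt(max(led), 1e-8)
  expect_named(led, c("carbon", "alkalinity", "calcium"))
  # spin-up flagging and annual summaries are coherent
  an <- annual_summary(res)
  expect_equal(nrow(an), 2)
  expect_true(all(is.finite(an$air_flux_ggc)))
  # tidy CSV export round-trips the daily table
  dir <- file.path(tempdir(), "lakecarb-out")
  write_result_csv(res, dir)
  back <- read.csv(file.path(dir, "daily.csv"))
  expect_equal(nrow(back), nrow(res$daily))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})

test_that("volume-weighted depth averages honour the slice", {
  g <- flat_grid(n = 10, dz = 2)
  v <- seq_len(10)
  expect_equal(depth_average(v, g, c(0, 10)), mean(1:5))
  expect_error(depth_average(v, g, c(500, 600)), "depth range")
  m <- cbind(v, v * 2)
  expect_equal(depth_average(m, g, c(0, 10)), c(mean(1:5), 2 * mean(1:5)))
})
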