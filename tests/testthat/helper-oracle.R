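# Brute-force speciation oracle: exhaustive pH grid scan minimising the
# absolute alkalinity residual, refined to 1e-4 pH resolution. Written from
# the equilibrium relations directly, independent of the package's
# bisection solver.
oracle_ph <- function(dic, tac, temp, ca = 0, background = 1e-3) {
  kc <- equilibrium_constants(temp)
  i <- ionic_strength(ca, hco3 = max(tac, 0), background = background)
  ph <- NA_real_
  for (it in 1:4) {
    g1 <- activity_coefficient(1L, i)
    g2 <- activity_coefficient(2L, i)
    resid <- function(p) {
      h <- 10^-p
      q1 <- kc$k1 / (g1 * h)
      q2 <- kc$k2 * g1 / (g2 * h)
      co2 <- dic * 1e-6 / (1 + q1 + q1 * q2)
      hco3 <- co2 * q1
      co3 <- hco3 * q2
      hco3 + 2 * co3 + kc$kw / (h * g1) - h / g1 - tac * 1e-6
    }
    coarse <- seq(3, 12, by = 0.01)
    p0 <- coarse[which.min(abs(resid(coarse)))]
    fine <- seq(max(3, p0 - 0.02), min(12, p0 + 0.02), by = 1e-4)
    ph <- fine[which.min(abs(resid(fine)))]
    h <- 10^-ph
    q1 <- kc$k1 / (g1 * h)
    q2 <- kc$k2 * g1 / (g2 * h)
    co2 <- dic * 1e-6 / (1 + q1 + q1 * q2)
    hco3 <- co2 * q1
    co3 <- hco3 * q2
    i <- ionic_strength(ca, hco3 * 1e6, co3 * 1e6, background = background)
  }
  ph
}

# Uniform-area column grid for analytic comparisons.
flat_grid <- function(n = 20, dz = 2, area = 1) {
  lake_grid(dz = dz, max_depth = n * dz, surface_area = area,
            hyps_max_depth = NULL)
}

# Random freshwater parcels within the solver's working envelope.
random_parcels <- function(n, seed = 1) {
  set.seed(seed)
  dic <- runif(n, 200, 3000)
  data.frame(dic = dic,
             tac = dic * runif(n, 0.7, 1.15),
             temp = runif(n, 2, 28),
             ca = runif(n, 0, 1500))
}

# Small fast configuration for column-level integration tests.
small_config <- function(years = 2, spinup_years = 0, seed = 7) {
  cfg <- default_config(years = years, spinup_years = spinup_years,
                        seed = seed)
  cfg$grid$dz <- 4
  cfg$store_profiles <- FALSE
  cfg
}
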