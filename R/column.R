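# 1D vertical column model: prescribed mixing and temperature, river
# exchange, prescribed net ecosystem production, calcite dynamics,
# carbonate speciation and surface gas exchange, advanced daily.
#
# Conventions used throughout: layer 1 is the surface, depths positive
# downward, air-water fluxes positive upward (out of the lake). Dissolved
# concentrations in mmol m^-3, per-layer absolute amounts in mmol.

.chem_error <- function(msg) {
  stop(errorCondition(msg, class = c("lakecarb_chem_error", "error")))
}
.config_error <- function(msg) {
  stop(errorCondition(msg, class = c("lakecarb_config_error", "error")))
}

#' Implicit vertical diffusion of a dissolved tracer
#'
#' Backward-Euler tridiagonal solve of the conservative diffusion operator
#' on the model grid, with zero-flux surface and bottom boundaries. The
#' column inventory of each tracer is conserved to round-off and no new
#' extrema are created.
#'
#' @param conc per-layer concentrations: a vector, or a layers-by-tracers
#'   matrix to diffuse several tracers with one factorisation.
#' @param kz vertical diffusivity at the n+1 layer interfaces, m^2 day^-1
#'   (the outermost two entries are ignored: zero-flux boundaries).
#' @param grid a [lake_grid()] object.
#' @param dt time step, days.
#' @return updated concentrations, same shape as `conc`.
#' @export
diffuse <- function(conc, kz, grid, dt = 1) {
  if (any(kz < 0)) .config_error("diffusivity must be >= 0 everywhere")
  n <- grid$n
  if (n == 1L) return(conc)
  x <- if (is.matrix(conc)) conc else matrix(conc, ncol = 1L)
  # conductance of interior interface i+1 (between layers i and i+1)
  g <- grid$area_edge[2:n] * kz[2:n] / (0.5 * (grid$dz[-n] + grid$dz[-1]))
  up <- c(0, g) * dt / grid$volume    # coupling to layer above
  dn <- c(g, 0) * dt / grid$volume    # coupling to layer below
  a <- -up                            # sub-diagonal coefficient (row i)
  b <- 1 + up + dn
  cc <- -dn                           # super-diagonal
  # Thomas algorithm with matrix right-hand side
  cp <- numeric(n)
  cp[1] <- cc[1] / b[1]
  x[1, ] <- x[1, ] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- cc[i] / m
    x[i, ] <- (x[i, ] - a[i] * x[i - 1, ]) / m
  }
  for (i in (n - 1):1) {
    x[i, ] <- x[i, ] - cp[i] * x[i + 1, ]
  }
  if (is.matrix(conc)) x else drop(x)
}

#' Apply net ecosystem production to the DIC field
#'
#' Positive NEP (net production) removes DIC; negative NEP (net respiration)
#' adds it. Alkalinity is unchanged. Removal is limited so DIC cannot be
#' driven below a small positive floor; the realised removal is returned for
#' the budget ledger.
#'
#' @param dic per-layer DIC, mmol m^-3.
#' @param nep per-layer net production rate, mmol C m^-3 day^-1.
#' @param dt time step, days.
#' @param floor minimum DIC retained, mmol m^-3 (default 1).
#' @return list with `dic` and `removed` (mmol m^-3, signed).
#' @export
apply_nep <- function(dic, nep, dt = 1, floor = 1) {
  removed <- pmin(nep * dt, dic - floor)
  list(dic = dic - removed, removed = removed)
}

#' River inflow and surface outflow
#'
#' Volume-conserving boundary exchange: the inflow adds tracer mass to the
#' intrusion layer (the layer within `intrusion_range` whose temperature is
#' closest to the river temperature, a density-matching proxy, or a fixed
#' layer if `intrusion_layer` is given), and the outflow removes surface
#' water at the same discharge.
#'
#' @param fields list of per-layer tracer vectors (e.g. dic, tac, ca).
#' @param river one-day river boundary condition: list or one-row data.frame
#'   with `discharge` (m^3 day^-1), `temp`, and one concentration
#'   (mmol m^-3) per entry of `fields`.
#' @param temp per-layer water temperature, degC.
#' @param grid a [lake_grid()] object.
#' @param dt time step, days.
#' @param intrusion_range depth window for the density-matched intrusion, m.
#' @param intrusion_layer optional fixed intrusion layer index.
#' @return list with updated `fields`, `in_mass`/`out_mass` (named mmol
#'   totals for the ledger) and `layer` (the intrusion layer used).
#' @export
river_exchange <- function(fields, river, temp, grid, dt = 1,
                           intrusion_range = c(5, 30),
                           intrusion_layer = NULL) {
  q <- river$discharge
  if (q < 0) .config_error("river discharge must be >= 0")
  nm <- names(fields)
  if (q == 0) {
    zero <- stats::setNames(numeric(length(nm)), nm)
    return(list(fields = fields, in_mass = zero, out_mass = zero, layer = NA))
  }
  if (is.null(intrusion_layer)) {
    cand <- which(grid$mids >= intrusion_range[1] &
                    grid$mids <= intrusion_range[2])
    lay <- cand[which.min(abs(temp[cand] - river$temp))]
  } else {
    lay <- intrusion_layer
  }
  # the interflow spreads over a band of layers around the matched depth
  # (Gaussian weights, ~5 m standard deviation), not a single thin layer
  z0 <- grid$mids[lay]
  w <- exp(-0.5 * ((grid$mids - z0) / 5)^2)
  w[abs(grid$mids - z0) > 12] <- 0
  w <- w * grid$volume
  w <- w / sum(w)
  vol_in <- q * dt
  in_mass <- out_mass <- stats::setNames(numeric(length(nm)), nm)
  for (f in nm) {
    add <- vol_in * river[[f]]
    rem <- vol_in * fields[[f]][1L]
    fields[[f]] <- fields[[f]] + add * w / grid$volume
    fields[[f]][1L] <- fields[[f]][1L] - rem / grid$volume[1L]
    in_mass[f] <- add
    out_mass[f] <- rem
  }
  list(fields = fields, in_mass = in_mass, out_mass = out_mass, layer = lay)
}

# Initialise the prognostic state from initial profiles.
init_state <- function(init, grid) {
  as_prof <- function(x) rep_len(x, grid$n)
  list(temp = as_prof(init$temp %||% 6),
       dic = as_prof(init$dic), tac = as_prof(init$tac),
       ca = as_prof(init$ca),
       particulate = numeric(grid$n), sediment = numeric(grid$n),
       day = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance the column model by one day
#'
#' Operator-split process order: vertical diffusion, river exchange, net
#' ecosystem production, calcite dynamics (precipitation, settling,
#' redissolution), speciation refresh, surface gas exchange. Gas exchange
#' comes last so the reported surface pCO2 reflects same-day chemistry.
#'
#' @param state prognostic state list (`temp`, `dic`, `tac`, `ca`,
#'   `particulate`, `sediment`, `day`).
#' @param frc one-day forcing: list with `temp` (n), `kz` (n+1), `nep` (n),
#'   `river` (see [river_exchange()]) and `atm_pco2`.
#' @param params run parameter list as from [default_config()] (`calcite`,
#'   `gas`, `chemistry`, `river` entries are used).
#' @param grid a [lake_grid()] object.
#' @param dt time step, days.
#' @return list with the updated `state` and a `diag` list: per-layer
#'   speciation (`spec`), precipitation `precip` (mmol m^-3), `dissolved`
#'   (mmol per layer), `air_flux` (mmol C m^-2 day^-1), ledger masses.
#' @export
step_day <- function(state, frc, params, grid, dt = 1) {
  cal <- params$calcite
  gas <- params$gas
  chem <- params$chemistry

  state$temp <- frc$temp

  ## 1. vertical diffusion of dissolved tracers
  m <- diffuse(cbind(state$dic, state$tac, state$ca), frc$kz, grid, dt)
  state$dic <- m[, 1]; state$tac <- m[, 2]; state$ca <- m[, 3]

  ## 2. river exchange
  rv <- river_exchange(list(dic = state$dic, tac = state$tac, ca = state$ca),
                       frc$river, state$temp, grid, dt,
                       intrusion_range = params$river$intrusion_range,
                       intrusion_layer = params$river$intrusion_layer)
  state$dic <- rv$fields$dic; state$tac <- rv$fields$tac
  state$ca <- rv$fields$ca

  ## 3. net ecosystem production
  np <- apply_nep(state$dic, frc$nep, dt)
  state$dic <- np$dic

  ## 4. calcite dynamics
  precip <- numeric(grid$n)
  dissolved <- numeric(grid$n)
  if (cal$enabled) {
    sp <- .speciate_column(state, frc$atm_pco2, chem)
    cp <- calcite_params(cal$omega_threshold, cal$rate,
                         cal$settling_velocity, cal$sediment_redissolution,
                         cal$redissolution_timescale)
    rate <- precipitation_rate(sp$omega_calcite, cp)
    ap <- apply_precipitation(state$dic, state$tac, state$ca,
                              state$particulate, rate, dt)
    state$dic <- ap$dic; state$tac <- ap$tac; state$ca <- ap$ca
    state$particulate <- ap$particulate
    precip <- ap$precipitated
    st <- settle_calcite(state$particulate, state$sediment, grid,
                         cp$settling_velocity, dt)
    state$particulate <- st$particulate
    state$sediment <- st$sediment
    if (cp$sediment_redissolution) {
      sp2 <- .speciate_column(state, frc$atm_pco2, chem)
      rd <- sediment_redissolution(state$sediment, state$dic, state$tac,
                                   state$ca, grid,
                                   cp$redissolution_timescale, dt,
                                   omega = sp2$omega_calcite)
      state$dic <- rd$dic; state$tac <- rd$tac; state$ca <- rd$ca
      state$sediment <- rd$sediment
      dissolved <- rd$dissolved
    }
  }

  ## 5. speciation refresh
  spec <- .speciate_column(state, frc$atm_pco2, chem)

  ## 6. surface gas exchange
  gp <- gas_params(gas$k600, gas$schmidt_scaling, gas$schmidt_exponent,
                   frc$atm_pco2, gas$chemical_enhancement)
  k <- piston_velocity(state$temp[1L], gp)
  enh <- enhancement_factor(spec$co2aq[1L], spec$hco3[1L], spec$co3[1L],
                            spec$ph[1L], state$temp[1L], k, gp)
  flux <- surface_flux(spec$co2aq[1L], state$temp[1L], gp, enh)
  state$dic[1L] <- state$dic[1L] -
    flux * dt * grid$area_edge[1L] / grid$volume[1L]

  state$day <- state$day + 1L
  list(state = state,
       diag = list(spec = spec, precip = precip, dissolved = dissolved,
                   air_flux = flux,
                   river_in = rv$in_mass, river_out = rv$out_mass,
                   nep_removed = sum(np$removed * grid$volume)))
}

# Column speciation with run-context error reporting.
.speciate_column <- function(state, atm_pco2, chem) {
  tryCatch(
    solve_speciation(state$dic, state$tac, state$temp, state$ca,
                     atm_pco2 = atm_pco2,
                     background = chem$background_ionic_strength),
    error = function(e) {
      .chem_error(sprintf("day %d: %s", state$day + 1L, conditionMessage(e)))
    })
}

#' Run a multi-year column simulation
#'
#' Builds the grid, generates (or accepts) the forcing, integrates the daily
#' process loop over `config$years` model years of 365 days, and returns the
#' diagnostics and budgets. The first `config$spinup_years` years are kept in
#' the output but flagged, and excluded by the analysis utilities
#' ([doy_climatology()], [seasonal_budget()], ...).
#'
#' @param config configuration list from [default_config()] (possibly
#'   modified or read from YAML via [read_config()]).
#' @param forcing optional pre-generated `forcing_series` (e.g. shared
#'   across the members of a paired experiment); defaults to
#'   `generate_forcing(config$forcing, grid)`.
#' @return object of class `experiment_result`.
#' @export
run_simulation <- function(config = default_config(), forcing = NULL) {
  config <- validate_config(config)
  grid <- do.call(lake_grid, config$grid)
  if (is.null(forcing)) {
    forcing <- generate_forcing(config$forcing, grid)
  }
  n_days <- forcing$n_days
  state <- init_state(forcing$init, grid)
  init_profile <- forcing$init
  clamp_tac <- !config$calcite$enabled &&
    identical(config$mute_mode, "clamp-tac")

  store <- isTRUE(config$store_profiles)
  prof_vars <- c("ph", "pco2", "dic", "tac", "omega_calcite", "precip")
  profiles <- if (store) {
    stats::setNames(lapply(prof_vars, function(v)
      matrix(NA_real_, grid$n, n_days)), prof_vars)
  }

  daily <- data.frame(
    day = seq_len(n_days),
    year = (seq_len(n_days) - 1L) %/% 365L + 1L,
    doy = (seq_len(n_days) - 1L) %% 365L + 1L)
  surf_vars <- c("temp", "dic", "tac", "ca", "ph", "pco2", "omega_co2",
                 "omega_calcite")
  for (v in surf_vars) daily[[v]] <- NA_real_
  daily$air_flux <- NA_real_          # mmol C m^-2 day^-1, positive out
  daily$precip_areal <- NA_real_     # mmol C m^-2 day^-1, column integral
  daily$precip_mol <- NA_real_        # mol C day^-1, whole lake
  daily$dissolved_mol <- NA_real_

  led <- list(river_in = c(dic = 0, tac = 0, ca = 0),
              river_out = c(dic = 0, tac = 0, ca = 0),
              air_out = 0, nep_removed = 0, precip = 0, dissolved = 0)
  inv0 <- .inventories(state, grid)

  for (d in seq_len(n_days)) {
    frc <- list(temp = forcing$temp[, d], kz = forcing$kz[, d],
                nep = forcing$nep[, d],
                river = forcing$river[d, , drop = FALSE],
                atm_pco2 = forcing$atm_pco2[d])
    res <- step_day(state, frc, config, grid)
    state <- res$state
    if (clamp_tac) state$tac <- rep_len(init_profile$tac, grid$n)
    dg <- res$diag

    sp <- dg$spec
    sel <- c("dic", "tac", "ca")
    surf <- function(x) depth_average(x, grid, c(0, 10))
    daily$temp[d] <- surf(state$temp)
    daily$dic[d] <- surf(state$dic); daily$tac[d] <- surf(state$tac)
    daily$ca[d] <- surf(state$ca)
    daily$ph[d] <- surf(sp$ph); daily$pco2[d] <- surf(sp$pco2)
    daily$omega_co2[d] <- surf(sp$omega_co2)
    daily$omega_calcite[d] <- surf(sp$omega_calcite)
    daily$air_flux[d] <- dg$air_flux
    daily$precip_areal[d] <- sum(dg$precip * grid$dz)
    daily$precip_mol[d] <- sum(dg$precip * grid$volume) / 1e3
    daily$dissolved_mol[d] <- sum(dg$dissolved) / 1e3

    led$river_in <- led$river_in + dg$river_in[sel]
    led$river_out <- led$river_out + dg$river_out[sel]
    led$air_out <- led$air_out + dg$air_flux * grid$area_edge[1L]
    led$nep_removed <- led$nep_removed + dg$nep_removed
    led$precip <- led$precip + sum(dg$precip * grid$volume)
    led$dissolved <- led$dissolved + sum(dg$dissolved)

    if (store) {
      profiles$ph[, d] <- sp$ph
      profiles$pco2[, d] <- sp$pco2
      profiles$dic[, d] <- state$dic
      profiles$tac[, d] <- state$tac
      profiles$omega_calcite[, d] <- sp$omega_calcite
      profiles$precip[, d] <- dg$precip
    }
  }

  structure(list(config = config, grid = grid, daily = daily,
                 profiles = profiles, ledger = led,
                 inventory_initial = inv0,
                 inventory_final = .inventories(state, grid),
                 state = state, forcing_spec = forcing$spec,
                 spinup_years = config$spinup_years,
                 years = config$years),
            class = "experiment_result")
}

# Whole-system inventories, mmol: carbon (DIC + suspended + sediment
# calcite), alkalinity (+2 per mol calcite), calcium (+1 per mol calcite).
.inventories <- function(state, grid) {
  calc <- sum(state$particulate * grid$volume) + sum(state$sediment)
  c(carbon = sum(state$dic * grid$volume) + calc,
    alkalinity = sum(state$tac * grid$volume) + 2 * calc,
    calcium = sum(state$ca * grid$volume) + calc)
}

#' Mass-conservation residuals of a finished run
#'
#' Compares the change in the whole-system carbon, alkalinity and calcium
#' inventories (water column plus suspended and sediment calcite) with the
#' accumulated boundary terms (river in/out, air-water flux, net ecosystem
#' production). Residuals are reported relative to the final inventory and
#' should be at round-off level (< 1e-8) for any run.
#'
#' @param result an [run_simulation()] result.
#' @return named numeric: relative residuals for carbon, alkalinity, calcium.
#' @export
carbon_ledger <- function(result) {
  led <- result$ledger
  d_inv <- result$inventory_final - result$inventory_initial
  expect <- c(
    carbon = unname(led$river_in["dic"] - led$river_out["dic"] -
                      led$air_out - led$nep_removed),
    alkalinity = unname(led$river_in["tac"] - led$river_out["tac"]),
    calcium = unname(led$river_in["ca"] - led$river_out["ca"]))
  abs(d_inv - expect) / abs(result$inventory_final)
}

#' @export
print.experiment_result <- function(x, ...) {
  yrs <- x$years
  cat(sprintf("<experiment_result> %d model years (%d spin-up), CP %s\n",
              yrs, x$spinup_years,
              if (x$config$calcite$enabled) "enabled" else "muted"))
  an <- annual_summary(x)
  if (nrow(an)) {
    cat(sprintf("  mean annual net CO2 efflux: %.2f Gg C yr^-1\n",
                mean(an$air_flux_ggc)))
    cat(sprintf("  mean annual calcite precipitated: %.1f g C m^-2 (epilimnion), %.2f Gg C (whole lake)\n",
                mean(an$precip_gc_m2), mean(an$precip_ggc)))
  }
  invisible(x)
}

#' Annual diagnostics of a run (analysis years only)
#'
#' Per analysis year (spin-up excluded): net air-water CO2 efflux in
#' Gg C yr^-1, annual calcite precipitated as column-integrated areal carbon
#' (g C m^-2 yr^-1) and as whole-lake mass (Gg C yr^-1), annual mean surface
#' (0-10 m) TAC (mol m^-3) and omega_CO2.
#'
#' @param result an [run_simulation()] result.
#' @param include_spinup include the spin-up years (default FALSE).
#' @return data.frame with one row per year.
#' @export
annual_summary <- function(result, include_spinup = FALSE) {
  d <- result$daily
  if (!include_spinup) d <- d[d$year > result$spinup_years, , drop = FALSE]
  a0 <- result$grid$area_edge[1L]
  out <- do.call(rbind, lapply(split(d, d$year), function(y) {
    data.frame(
      year = y$year[1L],
      air_flux_ggc = sum(y$air_flux) * a0 * 12e-12,    # mmol m^-2 -> Gg C
      precip_gc_m2 = sum(y$precip_mol) * 12 / a0,      # whole lake per m^2 surface
      precip_ggc = sum(y$precip_mol) * 12e-9,           # mol -> Gg C
      dissolved_ggc = sum(y$dissolved_mol) * 12e-9,
      tac_mol_m3 = mean(y$tac) / 1e3,
      omega_co2 = mean(y$omega_co2),
      ph = mean(y$ph))
  }))
  rownames(out) <- NULL
  out
}
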