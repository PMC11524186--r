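# Threshold-triggered calcite precipitation, particulate settling, and
# sediment redissolution. The reaction Ca2+ + 2 HCO3- <-> CaCO3 + CO2 + H2O
# removes 1 mol DIC, 2 mol alkalinity and 1 mol Ca per mol calcite formed,
# and returns them in the same ratios on dissolution.

#' Calcite-module parameters
#'
#' @param omega_threshold dimensionless calcite saturation index above which
#'   precipitation switches on (strict inequality; default 1.5).
#' @param rate volumetric precipitation rate once triggered,
#'   mmol C m^-3 day^-1 (default 2.5).
#' @param settling_velocity sinking speed of suspended calcite, m day^-1
#'   (default 1).
#' @param sediment_redissolution logical: return settled calcite to the
#'   overlying water (default TRUE; all authigenic calcite eventually
#'   redissolves in the sediment pore water).
#' @param redissolution_timescale e-folding time of the sediment calcite
#'   pool, days (default 30).
#' @return object of class `calcite_params`.
#' @export
calcite_params <- function(omega_threshold = 1.5, rate = 2.5,
                           settling_velocity = 1,
                           sediment_redissolution = TRUE,
                           redissolution_timescale = 30) {
  stopifnot(omega_threshold > 1, rate >= 0, settling_velocity >= 0,
            redissolution_timescale > 0)
  structure(list(omega_threshold = omega_threshold, rate = rate,
                 settling_velocity = settling_velocity,
                 sediment_redissolution = isTRUE(sediment_redissolution),
                 redissolution_timescale = redissolution_timescale),
            class = "calcite_params")
}

#' Calcite precipitation rate from the saturation index
#'
#' Zero at or below the trigger threshold, the constant configured rate
#' strictly above it.
#'
#' @param omega calcite saturation index (vectorised, >= 0).
#' @param params a [calcite_params()] object.
#' @return precipitation rate, mmol C m^-3 day^-1.
#' @export
precipitation_rate <- function(omega, params = calcite_params()) {
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  ifelse(omega > params$omega_threshold, params$rate, 0)
}

#' Apply calcite precipitation to water parcels
#'
#' Converts dissolved constituents into suspended calcite with exact reaction
#' stoichiometry: per mol calcite, DIC -1, alkalinity -2, calcium -1. The
#' requested amount is clipped so that no pool is driven negative (the most
#' limiting of DIC, TAC/2 and Ca caps the conversion).
#'
#' @param dic,tac,ca dissolved fields, mmol m^-3 (vectorised over layers).
#' @param particulate suspended calcite, mmol C m^-3.
#' @param rate precipitation rate per layer, mmol C m^-3 day^-1.
#' @param dt time step, days (> 0 unless zero-length step).
#' @return list with updated `dic`, `tac`, `ca`, `particulate`, and
#'   `precipitated` (the realised amount, mmol C m^-3).
#' @export
apply_precipitation <- function(dic, tac, ca, particulate, rate, dt = 1) {
  if (length(dt) != 1L || !is.finite(dt) || dt < 0) {
    stop("dt must be a single non-negative number of days", call. = FALSE)
  }
  p <- pmin(rate * dt, dic, tac / 2, ca)
  p <- pmax(p, 0)
  list(dic = dic - p, tac = tac - 2 * p, ca = ca - p,
       particulate = particulate + p, precipitated = p)
}

#' Settle suspended calcite through the water column
#'
#' First-order upwind advection at the settling velocity on the model grid.
#' In a basin with depth-varying horizontal area, the part of the downward
#' flux intercepted by the sediment shelf of each layer (the area lost
#' between the layer's top and bottom interfaces) is deposited into that
#' layer's sediment pool; on a uniform-area column only the bottom interface
#' deposits. Total calcite (water-column integral plus sediment) is conserved
#' to round-off.
#'
#' @param particulate suspended calcite per layer, mmol C m^-3.
#' @param sediment sediment calcite per layer, mmol (absolute amount; see
#'   [sediment_areal()] for the areal density).
#' @param grid a [lake_grid()] object.
#' @param velocity settling velocity, m day^-1.
#' @param dt time step, days; `velocity * dt` must not exceed the layer
#'   thickness (CFL condition).
#' @return list with updated `particulate`, `sediment`, and `deposited`
#'   (mmol per layer this step).
#' @export
settle_calcite <- function(particulate, sediment, grid, velocity, dt = 1) {
  if (velocity < 0) stop("settling velocity must be >= 0", call. = FALSE)
  if (velocity * dt > min(grid$dz)) {
    stop(sprintf(
      "settling CFL violated: velocity*dt = %.3g m exceeds layer thickness %.3g m",
      velocity * dt, min(grid$dz)), call. = FALSE)
  }
  if (velocity == 0 || dt == 0) {
    return(list(particulate = particulate, sediment = sediment,
                deposited = numeric(length(particulate))))
  }
  n <- grid$n
  a_top <- grid$area_edge[seq_len(n)]        # interface area above each layer
  a_bot <- grid$area_edge[seq_len(n) + 1L]   # interface area below each layer
  out <- velocity * dt * particulate * a_top             # mmol leaving layer i
  inflow <- c(0, velocity * dt * particulate[-n] * a_bot[-n])  # from above
  # of the outflow, the shelf (a_top - a_bot) share plus, for the bottom
  # layer, the remaining bottom-interface share, goes to sediment
  deposited <- velocity * dt * particulate * (a_top - a_bot)
  deposited[n] <- out[n]
  m <- particulate * grid$volume
  m_new <- m - out + inflow
  list(particulate = m_new / grid$volume,
       sediment = sediment + deposited,
       deposited = deposited)
}

#' Redissolve sediment calcite into the overlying water
#'
#' First-order decay of each sediment pool at the configured timescale; the
#' dissolved flux returns to the adjacent water layer with the reversed
#' precipitation stoichiometry (per mol calcite: DIC +1, alkalinity +2,
#' calcium +1). When the calcite saturation state of the overlying water is
#' supplied, the flux is additionally scaled by the undersaturation
#' max(0, 1 - omega) — the standard surface-controlled dissolution kinetics:
#' pore-water dissolution cannot drive the overlying water beyond calcite
#' saturation. Over long integrations every mol delivered to a sediment pool
#' under (on average) undersaturated water is returned, closing the calcite
#' loop.
#'
#' @inheritParams settle_calcite
#' @param dic,tac,ca dissolved fields, mmol m^-3.
#' @param timescale e-folding redissolution time, days.
#' @param omega optional per-layer calcite saturation index of the
#'   overlying water; if omitted the flux is unthrottled.
#' @return list with updated `dic`, `tac`, `ca`, `sediment`, and `dissolved`
#'   (mmol per layer this step).
#' @export
sediment_redissolution <- function(sediment, dic, tac, ca, grid,
                                   timescale = 30, dt = 1, omega = NULL) {
  if (any(sediment < -1e-9)) stop("sediment pool must be >= 0", call. = FALSE)
  gate <- if (is.null(omega)) 1 else pmax(0, pmin(1, 1 - omega))
  d <- pmin(sediment * dt / timescale * gate, sediment)   # mmol
  dc <- d / grid$volume                            # mmol m^-3 in each layer
  list(dic = dic + dc, tac = tac + 2 * dc, ca = ca + dc,
       sediment = sediment - d, dissolved = d)
}

#' Areal sediment calcite density
#'
#' Converts the absolute per-layer sediment amounts into mmol per square
#' metre of local sediment (shelf) area.
#'
#' @inheritParams settle_calcite
#' @return mmol m^-2 per layer (NA where a layer has no sediment shelf).
#' @export
sediment_areal <- function(sediment, grid) {
  shelf <- grid$area_edge[-(grid$n + 1L)] - grid$area_edge[-1L]
  shelf[grid$n] <- shelf[grid$n] + grid$area_edge[grid$n + 1L]
  ifelse(shelf > 0, sediment / shelf, NA_real_)
}
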