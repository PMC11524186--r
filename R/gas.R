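# Diffusive CO2 exchange across the lake-atmosphere interface.

#' Gas-exchange parameters
#'
#' @param k600 reference piston velocity at Schmidt number 600, m day^-1.
#' @param schmidt_scaling logical; if TRUE the piston velocity is rescaled by
#'   (Sc(T)/600)^(-schmidt_exponent), otherwise `k600` is used unchanged at
#'   all temperatures (the default: a constant piston velocity).
#' @param schmidt_exponent dimensionless exponent (default 0.5, the
#'   wavy-surface value).
#' @param atm_pco2 atmospheric CO2 partial pressure, uatm (default 350).
#' @param chemical_enhancement logical; if TRUE the flux is multiplied by a
#'   Hoover-Berkshire-type enhancement factor (default FALSE).
#' @return object of class `gas_params`.
#' @export
gas_params <- function(k600 = 1.0, schmidt_scaling = FALSE,
                       schmidt_exponent = 0.5, atm_pco2 = 350,
                       chemical_enhancement = FALSE) {
  stopifnot(k600 > 0, atm_pco2 > 0)
  structure(list(k600 = k600, schmidt_scaling = isTRUE(schmidt_scaling),
                 schmidt_exponent = schmidt_exponent, atm_pco2 = atm_pco2,
                 chemical_enhancement = isTRUE(chemical_enhancement)),
            class = "gas_params")
}

#' Schmidt number of CO2 in fresh water
#'
#' Fourth-order polynomial fit (Wanninkhof-type, normalised to 600 at 20 degC
#' in fresh water).
#'
#' @param temp temperature, degC (vectorised).
#' @return dimensionless Schmidt number.
#' @export
schmidt_number <- function(temp) {
  1923.6 - 125.06 * temp + 4.3773 * temp^2 -
    0.085681 * temp^3 + 0.00070284 * temp^4
}

#' Gas-transfer (piston) velocity
#'
#' @param temp surface temperature, degC.
#' @param params a [gas_params()] object.
#' @return piston velocity, m day^-1.
#' @export
piston_velocity <- function(temp, params = gas_params()) {
  if (!params$schmidt_scaling) {
    return(rep_len(params$k600, length(temp)))
  }
  params$k600 * (schmidt_number(temp) / 600)^(-params$schmidt_exponent)
}

#' Chemical enhancement of CO2 gas exchange
#'
#' Hoover-Berkshire film model: in alkaline water CO2 reacts with OH- (and
#' hydrates) within the diffusive boundary layer, steepening the gradient.
#' Enhancement E = tau / ((tau - 1) + tanh(q)/q) with
#' tau = 1 + CO2/(HCO3 + CO3), q = delta * sqrt(r tau / D), film thickness
#' delta = D/k, hydration rate r = k_CO2(T) + k_OH(T) * a(OH-).
#'
#' @param co2aq,hco3,co3 surface speciation, mmol m^-3.
#' @param ph surface pH (activity scale).
#' @param temp surface temperature, degC.
#' @param k piston velocity, m day^-1.
#' @param params a [gas_params()] object; returns 1 when
#'   `chemical_enhancement` is FALSE.
#' @return dimensionless factor >= 1.
#' @export
enhancement_factor <- function(co2aq, hco3, co3, ph, temp, k,
                               params = gas_params()) {
  if (!params$chemical_enhancement) {
    return(rep_len(1, max(length(co2aq), length(temp))))
  }
  tk <- temp + 273.15
  kw <- equilibrium_constants(temp)$kw
  a_oh <- kw / 10^(-ph)                          # OH- activity, mol L^-1
  k_co2 <- exp(1246.98 - 6.19e4 / tk - 183.0 * log(tk))   # s^-1 (hydration)
  k_oh <- 10^(13.635 - 2895 / tk)                # L mol^-1 s^-1
  r <- k_co2 + k_oh * a_oh                       # s^-1
  d_co2 <- 5.019e-6 * exp(-19510 / (8.314 * tk)) # m^2 s^-1 (Arrhenius fit)
  k_ms <- k / 86400                              # m s^-1
  delta <- d_co2 / k_ms
  tau <- 1 + co2aq / (hco3 + co3)
  q <- delta * sqrt(r * tau / d_co2)
  e <- tau / ((tau - 1) + tanh(q) / q)
  pmax(e, 1)
}

#' Air-water CO2 flux at the lake surface
#'
#' F = E * k * (CO2aq - KH * pCO2_atm), positive upward (efflux to the
#' atmosphere). The sign of the flux is the sign of (omega_CO2 - 1).
#'
#' @param co2aq surface dissolved CO2, mmol m^-3.
#' @param temp surface temperature, degC.
#' @param params a [gas_params()] object.
#' @param enhancement dimensionless multiplicative factor (default 1).
#' @return flux in mmol C m^-2 day^-1.
#' @export
surface_flux <- function(co2aq, temp, params = gas_params(), enhancement = 1) {
  k <- piston_velocity(temp, params)
  kh <- equilibrium_constants(temp)$kh
  enhancement * k * (co2aq - kh * params$atm_pco2)
}
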