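# Freshwater carbonate-system engine.
#
# All concentrations are mmol m^-3 (numerically equal to umol L^-1), pCO2 in
# uatm (treated as synonymous with ppm), temperatures in degrees Celsius.
# Internally species are handled in mol L^-1 on the free hydrogen-ion
# (activity) scale; the molality/molarity distinction is neglected
# (density taken as 1 kg L^-1), which is a sub-permille error in fresh water.

#' Temperature-dependent carbonate equilibrium constants
#'
#' Evaluates a consistent published freshwater set of thermodynamic constants:
#' the Plummer & Busenberg (1982) fits for the first and second dissociation
#' constants of carbonic acid (`k1`, `k2`), the calcite solubility product
#' (`ksp`) and the Henry's law constant of CO2 (`kh`), together with a
#' Harned-type fit for the ion product of water (`kw`). All are on the
#' activity (free) scale, in mol L^-1 units; `kh` is in
#' mol L^-1 atm^-1, numerically equal to mmol m^-3 uatm^-1.
#'
#' @param temp water temperature, degrees Celsius (vectorised); must lie in
#'   \[-5, 40\], the validity range adopted for the fits.
#' @return a list with numeric components `k1`, `k2`, `kw`, `kh`, `ksp`, each
#'   the same length as `temp`.
#' @examples
#' kc <- equilibrium_constants(25)
#' -log10(kc$k1)  # ~6.35
#' @export
equilibrium_constants <- function(temp) {
  if (any(!is.finite(temp)) || any(temp < -5) || any(temp > 40)) {
    stop("temperature out of range [-5, 40] degC", call. = FALSE)
  }
  tk <- temp + 273.15
  lt <- log10(tk)
  k1 <- 10^(-356.3094 - 0.06091964 * tk + 21834.37 / tk +
              126.8339 * lt - 1684915 / tk^2)
  k2 <- 10^(-107.8871 - 0.03252849 * tk + 5151.79 / tk +
              38.92561 * lt - 563713.9 / tk^2)
  kh <- 10^(108.3865 + 0.01985076 * tk - 6919.53 / tk -
              40.45154 * lt + 669365 / tk^2)
  ksp <- 10^(-171.9065 - 0.077993 * tk + 2839.319 / tk + 71.595 * lt)
  kw <- 10^(-283.9710 - 0.05069842 * tk + 13323.00 / tk +
              102.24447 * lt - 1119669 / tk^2)
  list(k1 = k1, k2 = k2, kw = kw, kh = kh, ksp = ksp)
}

#' Molality-scale ionic strength of a parcel
#'
#' I = 1/2 * sum(c_i z_i^2) over the explicitly modelled ions (Ca2+, HCO3-,
#' CO3^2-) plus a constant background term standing in for the unmodelled
#' major ions (Mg2+, Na+, SO4^2-, Cl-, ...).
#'
#' @param ca,hco3,co3 ion concentrations, mmol m^-3 (vectorised).
#' @param background background ionic strength, mol kg^-1 (default 1e-3).
#' @return ionic strength, mol kg^-1.
#' @export
ionic_strength <- function(ca, hco3 = 0, co3 = 0, background = 1e-3) {
  if (any(background < 0)) stop("background ionic strength must be >= 0", call. = FALSE)
  0.5e-6 * (4 * ca + hco3 + 4 * co3) + background
}

#' Davies activity coefficient
#'
#' Single-ion activity coefficient from the Davies equation,
#' log10(gamma) = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I) with A = 0.509.
#' Valid for ionic strengths below ~0.1 mol kg^-1, which covers hardwater
#' lakes comfortably.
#'
#' @param charge integer ionic charge (sign irrelevant: depends on z^2 only).
#' @param i ionic strength, mol kg^-1 (>= 0).
#' @return dimensionless activity coefficient, 1 at infinite dilution.
#' @export
activity_coefficient <- function(charge, i) {
  if (any(i < 0)) stop("ionic strength must be >= 0", call. = FALSE)
  si <- sqrt(i)
  10^(-0.509 * charge^2 * (si / (1 + si) - 0.3 * i))
}

#' Calcite saturation index
#'
#' Omega = a(Ca2+) a(CO3^2-) / Ksp, with activities from the Davies model.
#' Omega > 1 means thermodynamic supersaturation with respect to calcite.
#'
#' @param ca calcium concentration, mmol m^-3.
#' @param co3 carbonate-ion concentration, mmol m^-3.
#' @param temp temperature, degC.
#' @param i ionic strength, mol kg^-1.
#' @return dimensionless saturation index (vectorised).
#' @export
omega_calcite <- function(ca, co3, temp, i) {
  ksp <- equilibrium_constants(temp)$ksp
  g2 <- activity_coefficient(2L, i)
  (g2 * ca * 1e-6) * (g2 * co3 * 1e-6) / ksp
}

# Alkalinity residual at hydrogen-ion activity `h` for a parcel, mol L^-1.
# g1/g2 are monovalent/divalent activity coefficients. Used by the solver.
.alk_residual <- function(h, dic_mol, tac_mol, kc, g1, g2) {
  q1 <- kc$k1 / (g1 * h)
  q2 <- kc$k2 * g1 / (g2 * h)
  co2 <- dic_mol / (1 + q1 + q1 * q2)
  hco3 <- co2 * q1
  co3 <- hco3 * q2
  oh <- kc$kw / (h * g1)
  hco3 + 2 * co3 + oh - h / g1 - tac_mol
}

#' Solve carbonate speciation of water parcels
#'
#' Finds the pH at which the carbonate alkalinity balance
#' \[HCO3-\] + 2\[CO3^2-\] + \[OH-\] - \[H+\] equals the prescribed total
#' alkalinity, partitioning DIC among CO2(aq), HCO3- and CO3^2- with
#' activity-corrected equilibrium constants. The root is isolated by fixed
#' bisection on pH in \[3, 12\] (55 halvings, final bracket ~2.5e-16 pH
#' units, well inside the 1e-8 contract), with the ionic strength and Davies
#' coefficients refreshed in an outer loop from the solved speciation.
#'
#' All arguments are vectorised over parcels.
#'
#' @param dic dissolved inorganic carbon, mmol m^-3 (> 0).
#' @param tac total alkalinity, mmol m^-3 as charge-equivalents.
#' @param temp temperature, degC.
#' @param ca dissolved calcium, mmol m^-3 (enters the ionic strength and the
#'   calcite saturation index).
#' @param atm_pco2 atmospheric reference pCO2, uatm, for `omega_co2`.
#' @param background background ionic strength, mol kg^-1.
#' @param activity_iter outer activity-refinement iterations (default 3).
#' @return a data.frame with one row per parcel: `ph`, `co2aq`, `hco3`,
#'   `co3` (mmol m^-3), `pco2` (uatm), `omega_calcite`, `omega_co2`,
#'   `ionic_strength` (mol kg^-1).
#' @examples
#' solve_speciation(dic = 1800, tac = 1700, temp = 6)
#' @export
solve_speciation <- function(dic, tac, temp, ca = 0, atm_pco2 = 350,
                             background = 1e-3, activity_iter = 3L) {
  n <- max(length(dic), length(tac), length(temp), length(ca))
  dic <- rep_len(dic, n); tac <- rep_len(tac, n)
  temp <- rep_len(temp, n); ca <- rep_len(ca, n)
  if (any(!is.finite(dic)) || any(dic <= 0)) {
    stop("dic must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(tac))) stop("tac must be finite", call. = FALSE)
  if (any(ca < 0)) stop("ca must be >= 0", call. = FALSE)
  kc <- equilibrium_constants(temp)
  dic_mol <- dic * 1e-6
  tac_mol <- tac * 1e-6

  # initial ionic strength guess: all alkalinity as bicarbonate
  i <- ionic_strength(ca, hco3 = pmax(tac, 0), co3 = 0, background = background)
  ph <- rep(7, n)
  for (outer in seq_len(activity_iter + 1L)) {
    g1 <- activity_coefficient(1L, i)
    g2 <- activity_coefficient(2L, i)
    lo <- rep(3, n); hi <- rep(12, n)
    flo <- .alk_residual(10^-lo, dic_mol, tac_mol, kc, g1, g2)
    fhi <- .alk_residual(10^-hi, dic_mol, tac_mol, kc, g1, g2)
    bad <- flo * fhi > 0
    if (any(bad)) {
      stop(sprintf(
        "alkalinity is chemically infeasible for the given DIC in %d parcel(s) (first at index %d: dic=%.3g, tac=%.3g)",
        sum(bad), which(bad)[1L], dic[which(bad)[1L]], tac[which(bad)[1L]]),
        call. = FALSE)
    }
    # residual is increasing in pH (decreasing in h)
    for (it in 1:55) {
      mid <- 0.5 * (lo + hi)
      fm <- .alk_residual(10^-mid, dic_mol, tac_mol, kc, g1, g2)
      up <- fm < 0          # root above mid
      lo <- ifelse(up, mid, lo)
      hi <- ifelse(up, hi, mid)
    }
    ph <- 0.5 * (lo + hi)
    h <- 10^-ph
    q1 <- kc$k1 / (g1 * h)
    q2 <- kc$k2 * g1 / (g2 * h)
    co2 <- dic_mol / (1 + q1 + q1 * q2)
    hco3 <- co2 * q1
    co3 <- hco3 * q2
    i_new <- ionic_strength(ca, hco3 * 1e6, co3 * 1e6, background = background)
    if (max(abs(i_new - i)) < 1e-12) { i <- i_new; break }
    i <- i_new
  }
  g2 <- activity_coefficient(2L, i)
  pco2 <- co2 * 1e6 / kc$kh    # (mmol m^-3) / (mmol m^-3 uatm^-1)
  data.frame(
    ph = ph,
    co2aq = co2 * 1e6,
    hco3 = hco3 * 1e6,
    co3 = co3 * 1e6,
    pco2 = pco2,
    omega_calcite = omega_calcite(ca, co3 * 1e6, temp, i),
    omega_co2 = pco2 / atm_pco2,
    ionic_strength = i
  )
}

#' Recover DIC from pH and alkalinity
#'
#' Inverse of the speciation solve: given a pH (hydrogen-ion activity scale)
#' and total alkalinity, returns the DIC and species split consistent with
#' the same constants and activity model. Used for round-trip checks and for
#' constructing parcels lying on a prescribed pH grid.
#'
#' @inheritParams solve_speciation
#' @param ph pH on the activity scale.
#' @return data.frame with `dic`, `co2aq`, `hco3`, `co3` (mmol m^-3).
#' @export
dic_from_ph_tac <- function(ph, tac, temp, ca = 0, background = 1e-3,
                            activity_iter = 3L) {
  n <- max(length(ph), length(tac), length(temp), length(ca))
  ph <- rep_len(ph, n); tac <- rep_len(tac, n)
  temp <- rep_len(temp, n); ca <- rep_len(ca, n)
  kc <- equilibrium_constants(temp)
  h <- 10^-ph
  i <- ionic_strength(ca, hco3 = pmax(tac, 0), co3 = 0, background = background)
  for (outer in seq_len(activity_iter + 1L)) {
    g1 <- activity_coefficient(1L, i)
    g2 <- activity_coefficient(2L, i)
    q1 <- kc$k1 / (g1 * h)
    q2 <- kc$k2 * g1 / (g2 * h)
    carb_alk <- tac * 1e-6 - kc$kw / (h * g1) + h / g1
    hco3 <- carb_alk / (1 + 2 * q2)
    if (any(hco3 <= 0)) {
      stop("alkalinity too low to carry carbonate species at this pH", call. = FALSE)
    }
    co3 <- hco3 * q2
    co2 <- hco3 / q1
    i <- ionic_strength(ca, hco3 * 1e6, co3 * 1e6, background = background)
  }
  data.frame(dic = (co2 + hco3 + co3) * 1e6,
             co2aq = co2 * 1e6, hco3 = hco3 * 1e6, co3 = co3 * 1e6)
}
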