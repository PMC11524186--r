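---
title: "Calcite precipitation and the inorganic carbon cycle of a hardwater lake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcite precipitation and the inorganic carbon cycle of a hardwater lake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lakecarb` simulates the inorganic carbon cycle of a deep, hardwater,
warm-monomictic lake on a fixed vertical grid (2-m layers, depth positive
downward, a linear-in-depth hypsometric taper from 580 km^2 at the surface
to zero at 309 m) with a daily time step. The prognostic fields are
temperature (prescribed), dissolved inorganic carbon (DIC), total
alkalinity (TAC, carbonate alkalinity + OH^- − H^+; borate and organic
contributions are ignored in fresh water), dissolved calcium, suspended
calcite, and per-layer sediment calcite. Each day the operator-split
process loop applies, in order: implicit vertical diffusion, river
exchange, net ecosystem production (NEP), calcite dynamics (precipitation,
settling, sediment redissolution), a speciation refresh, and surface gas
exchange. Gas exchange runs last so the reported surface pCO2 reflects
same-day chemistry; at a one-day step the split order changes annual
budgets by far less than the parametric uncertainty.

## Carbonate chemistry

Speciation is solved per parcel from (DIC, TAC, T, Ca). The equilibrium
constants are a consistent published freshwater set — the Plummer &
Busenberg (1982) fits for K1, K2, the calcite solubility product and the
CO2 Henry constant, and a Harned-type fit for Kw — evaluated on the
activity scale and frozen as a versioned CSV fixture
(`inst/extdata/carbonate_constants.csv`) so tests pin exact values. Ion
activities use the Davies equation with the ionic strength computed from
the modelled ions (Ca^2+, HCO3^-, CO3^2-) plus a configurable background
term (default 1e-3 mol kg^-1) standing in for the unmodelled major ions;
the Davies model is adequate below I ~ 0.1 mol kg^-1, which covers
hardwater lakes. The molality/molarity distinction is neglected (density
1 kg L^-1). The pH solving the alkalinity balance is isolated by fixed
vectorised bisection on [3, 12] (55 halvings, i.e. far below the 1e-8 pH
tolerance contract), with activity coefficients refreshed from the solved
speciation in a short outer loop. Infeasible (DIC, TAC) pairs — no sign
change of the alkalinity residual in the bracket — raise a classed
chemistry error naming the offending parcel, which the column model
augments with the simulation day.

Two saturation indices are diagnosed: Omega_calcite =
a(Ca^2+) a(CO3^2-)/Ksp, and Omega_CO2 = pCO2/pCO2_atm, the CO2 saturation
ratio against the atmospheric reference (350 ppm by default, with ppm and
uatm used interchangeably).

## The calcite module

Precipitation is threshold-triggered and constant-rate: zero at or below
Omega_calcite = 1.5 (strictly — equality precipitates nothing) and
2.5 mmol C m^-3 day^-1 above it, in every layer that exceeds the
threshold, clipped so that no reactant pool (DIC, TAC/2, Ca) goes
negative. Per mole of calcite the reaction moves DIC by −1, alkalinity by
−2 and calcium by −1; suspended calcite gains +1. Suspended calcite sinks
at 1 m day^-1 (first-order upwind, CFL-checked); in the tapering basin the
part of the downward flux intercepted by each layer's sediment shelf (the
interface-area difference) deposits into that layer's sediment pool, which
on a uniform-area column reduces to deposition through the bottom
interface only.

Sediment calcite redissolves back into the overlying water with reversed
stoichiometry (+1 DIC, +2 TAC, +1 Ca per mole), closing the calcite loop:
no authigenic calcite is permanently buried. The kinetics are first-order
in the sediment stock (intrinsic timescale 360 days) scaled by the
undersaturation of the overlying water, max(0, 1 − Omega). The saturation
gate is a deliberate design choice: with a cone-like hypsometry the entire
settling flux converges into vanishing near-bottom volumes, and ungated
return would drive bottom water far past calcite saturation — a
thermodynamic impossibility for dissolution — and set up a spurious
precipitation/dissolution churn. Gated, deep water relaxes toward
Omega ~ 1 and the return flux concentrates in the undersaturated mixing
season; the effective return time is of order a year, so the sediment
stock holds a few years of production in transit, and no calcite is
permanently lost from the loop.

## Gas exchange

The surface flux is F = E k (CO2aq − KH pCO2_atm), positive upward. The
transfer velocity is Schmidt-scaled by default, k = k600 (Sc/600)^(-2/3)
with k600 = 1 m day^-1 and the freshwater Schmidt polynomial — about
0.6 m day^-1 over 6 degC winter water and 1.05 m day^-1 in summer. A
constant piston velocity is available behind a flag
(`gas$schmidt_scaling = FALSE`); we default to the scaled form because the
winter/summer asymmetry of the transfer velocity is what lets the model
carry a realistic winter CO2 oversaturation while still exchanging
vigorously over the warm, near-equilibrium summer surface. Chemical
enhancement of CO2 exchange at high pH (a Hoover-Berkshire film model fed
by CO2 hydration and OH^- reaction kinetics) is implemented but off by
default, since the reference parametrisation it emulates did not state it
was active.

## Transport, river and NEP

Vertical diffusion is backward-Euler tridiagonal in conservative form
(interface areas times diffusivity), with zero-flux boundaries: inventories
are conserved to round-off and no new extrema appear. The river inflow
intrudes as a Gaussian-weighted band (~5 m standard deviation) around the
layer whose temperature best matches the river within a configurable depth
window (default 30-50 m: the summer glacial interflow is cold and
sediment-laden and plunges below the productive layer); the outflow removes
surface water at the same discharge, so tracer mass bookkeeping is exact.
NEP is prescribed forcing: positive net production removes DIC, respiration
below adds it, and alkalinity is untouched by NEP (nitrate-assimilation
alkalinity effects are out of scope).

# The synthetic forcing

The generator produces deterministic seasonal climatologies plus small
seeded AR(1) noise (surface temperature sd 0.3 degC; production multiplier
sd 8%) — the seed fully determines the series, and paired CP/noCP runs
always share one realisation. It emulates a warm-monomictic Geneva-like
basin rather than replaying observed meteorology: the acceptance surface is
mechanism and climatology shape, not hindcast skill.

* **Thermal / mixing structure.** Surface temperature runs 6-23 degC with
  its maximum near day 220. The mixed-layer depth follows a control-point
  seasonal cycle: full overturn near day 40, slow spring restratification
  (the mixed layer is still ~40 m in mid-May), a 9-11 m summer thermocline,
  and progressive fall deepening. Diffusivity interpolates between
  5000 m^2 day^-1 (convectively mixing layer) and 0.03 m^2 day^-1
  (quiescent interior) in log space — thermocline diffusivities drop by
  orders of magnitude over a few metres, which a linear blend cannot
  represent, and a leaky thermocline otherwise feeds the supersaturated
  band with a spurious alkalinity flux.
* **NEP.** Production has two seasonal components — a spring bloom
  (Gaussian, peak day 85, while the mixed layer is still tens of metres
  deep) carrying 45% of the annual total, and a stratified-season window
  (days 160-290) — with an e-folding production depth of 18 m, shallow
  respiration (8 m scale) and deep respiration confined below 30 m (the
  mineralisation of exported and river-borne organic carbon; 1.5x the 0-30
  m net target, i.e. more than the autochthonous export alone, as expected
  for a lake receiving substantial river organic carbon). The three
  amplitudes are solved from three integral constraints: annual net 0-30 m
  NEP equals 80 g C m^-2, half of it accrues in the top 10 m, and the
  below-30 m return equals its configured fraction. The seasonal split
  matters: production over a deep spring mixed layer consumes the winter
  CO2 stock with little pH rise, while the same drain concentrated under a
  10-m summer thermocline is what pushes the surface over the calcite
  threshold.
* **River.** Mean discharge is set by the 11-year residence time, with a
  30% glacial-melt seasonal swing peaking near day 170 and a 5-8 degC
  temperature cycle. River DIC is 1.82 mol m^-3 with 96% as bicarbonate
  (TAC = 0.96 DIC) and calcium 0.8 mol m^-3.
* **Initial state.** Uniform winter profiles: DIC 1800, TAC 1740, Ca 800
  mmol m^-3 at 6 degC. Calcium deserves emphasis: it is *not*
  observationally constrained here. 0.8 mol m^-3 is the charge-balance
  floor for the prescribed alkalinity (2 Ca ~ TAC); real hardwater lakes
  carry more calcium balanced by sulfate, and any site application should
  set `river$ca`/`init$ca` from data.

With these defaults the reference run reproduces the intended climatology:
winter surface DIC ~1730-1760 mmol m^-3 at pH ~8.0 and 2-2.3x CO2
supersaturation; summer surface pH <= 8.5 near gas equilibrium with calcite
supersaturation confined to roughly the upper 15 m from late spring to
early fall; annual calcite precipitation ~42 g C m^-2 (about 24 Gg C
whole-lake); and an annual net efflux of ~16 Gg C. Muting the calcite
module under identical forcing sends summer pH above 9, leaves the surface
undersaturated through fall, and drops the net annual efflux to ~3 Gg C.

What the generator does **not** emulate: observed meteorological
variability and trends, episodic storm deepening, ice, the occasional
multi-year gaps between complete overturns of very deep lakes, or lateral
variability. Passing tests therefore demonstrate mechanism and seasonal
structure, not hindcast fidelity for any specific year.

# Design decisions and numerical choices

* **Calibration target of the defaults.** The spring/summer split of
  production, the restratification timing, and the respiration depth
  structure were chosen (once) so that the reference climatology above
  emerges; they are scientific choices about a typical deep hardwater lake,
  documented here because the simulator's headline numbers (areal calcite,
  efflux contrast) are sensitive to them. An instructive emergent property:
  because precipitation is flat-rate above a threshold, annual calcite
  production approximately equals the net CO2 drawdown that occurs in
  supersaturated water — the seasonal and vertical placement of NEP, not
  the threshold value, is what sets the calcite budget.
* **Saturation-gated redissolution** (see above): the plain first-order
  form is recovered by omitting the `omega` argument.
* **365-day calendar** for synthetic runs; real-date inputs pool Feb 29
  onto day 59 (`doy365()`).
* **Seasons** are meteorological (DJF/MAM/JJA/SON) with December pooled
  into the same model year's DJF, so annual budgets equal the sum of their
  four seasons exactly.
* **Annual mean Omega_CO2** for the alkalinity sweep is the unweighted mean
  of daily 0-10 m volume-weighted values, regressed against the *realised*
  annual mean surface alkalinity (precipitation itself draws alkalinity
  down, so the nominal scaling factor is not the abscissa).
* **Muting variants.** The default mute zeroes the precipitation and
  dissolution rates (mechanistically minimal); `mute_mode = "clamp-tac"`
  additionally pins TAC to its initial profile each day, mirroring the
  "fixed alkalinity" phrasing sometimes used for such experiments. The
  clamp variant deliberately breaks alkalinity conservation and is excluded
  from the ledger checks.
* **Degenerate inputs.** The solver brackets pH in [3, 12] and raises a
  classed error outside it; precipitation is clipped at reactant
  exhaustion; settling is CFL-checked; diffusivities must be non-negative;
  configuration errors carry their own condition class (CLI exit code 2,
  chemistry errors exit 3).
* **Problem sizes.** The packaged experiments use a 154-layer column and
  5 analysis years after a 2-year spin-up (the spin-up discards the
  initial-profile transient); the tests use the same reference run shared
  across checks, plus small uniform columns for analytic comparisons.
  Multi-year drift of a few mmol m^-3 yr^-1 in DIC remains at these run
  lengths — the synthetic boundary conditions are not an exact steady
  state of the model — which is why diagnostics average over the analysis
  years rather than a single year.

# Known limitations

* No hydrodynamic closure, ice, nutrient or plankton dynamics: temperature,
  mixing and NEP are forcing, so biological feedbacks (e.g. nutrient
  limitation shortening a bloom) cannot emerge.
* The constant-rate calcite parametrisation is a site-calibrated
  simplification; both the threshold and the rate should be recalibrated
  per lake, and nucleation/crystal dynamics are out of scope.
* The carbonate constants and activity model are a standard freshwater
  set, not a replication of any particular geochemical code's
  configuration; exact numeric agreement of speciation with other codes is
  not attempted.
* The bundled regression references (`reference_fits()`) are comparison
  constants from the literature, not quantities this package can
  recompute without the corresponding observational data.
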