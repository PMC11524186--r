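# Synthetic forcing generator: deterministic seasonal climatology plus small
# seeded AR(1) noise, emulating a warm-monomictic, moderately alkaline,
# Geneva-like lake. Stands in for hydrodynamic-model output and monitored
# boundary conditions so that every downstream module is testable without
# any external dataset.

#' Synthetic forcing specification
#'
#' All defaults describe the reference lake: a deep monomictic basin that
#' mixes fully in late winter (surface ~6 degC, high DIC, pCO2 around three
#' times atmospheric), stratifies with a 10-15 m summer thermocline, reaches
#' ~23 degC at the surface, and drains a carbonate catchment through a river
#' carrying ~1.9 mol m^-3 DIC of which 96% is bicarbonate. Net ecosystem
#' production integrates to `nep_areal_target` g C m^-2 yr^-1 over 0-30 m,
#' with respiration returning `deep_resp_fraction` of it below 30 m.
#'
#' @param years number of 365-day model years.
#' @param seed integer; fully determines the noise realisation.
#' @param thermal list: `t_winter`, `t_summer` (surface extremes, degC),
#'   `t_deep` (deep-water temperature), `peak_doy` (day of surface maximum),
#'   `sharpness` (m, width of the thermal gradient at the mixed-layer
#'   base).
#' @param mixing list: `kz_mixed`, `kz_deep` (m^2 day^-1), `sharpness` (m,
#'   width of the mixed-to-quiescent diffusivity transition; sharper than the
#'   thermal gradient so mixed-layer chemistry does not leak into the
#'   metalimnion), `ml_depth` (data.frame doy/depth control points of the
#'   mixed-layer seasonal cycle).
#' @param nep list: `photic_scale`, `resp_shallow_scale`, `resp_deep_scale`
#'   (e-folding depths, m, of production and of epilimnetic and deep
#'   respiration), `areal_target` (net 0-30 m NEP, g C m^-2 yr^-1),
#'   `ml_share` (fraction of the net target accruing in the top 10 m; the
#'   rest accrues in the deep-chlorophyll-maximum band),
#'   `deep_resp_fraction` (respiratory return below 30 m as a fraction of
#'   the target; values above 1 represent mineralisation of river-borne
#'   organic carbon in addition to autochthonous export), `spring_frac`
#'   (share of annual production in the spring bloom, which occurs over a
#'   still-deep mixed layer and consumes the winter CO2 excess),
#'   `spring_peak`, `spring_width` (DOY centre and width of the bloom),
#'   `prod_start`, `prod_length` (DOY window of the stratified-season
#'   production), `resp_lag` (days), `resp_base` (wintertime respiration
#'   floor, fraction of peak).
#' @param river list: `residence_years`, `dic`, `bicarb_fraction`, `ca`
#'   (mmol m^-3), `q_amplitude` (relative seasonal discharge swing),
#'   `q_peak_doy`, `t_min`, `t_max` (river temperature range, degC).
#' @param init list: initial uniform profiles `dic`, `tac`, `ca`
#'   (mmol m^-3) and `temp` (degC).
#' @param atm_pco2 atmospheric CO2, uatm (constant by default; a vector of
#'   length years*365 may be supplied).
#' @param noise list: `t_sd`, `t_phi` (surface-temperature AR(1)),
#'   `prod_sd`, `prod_phi` (production multiplier AR(1)).
#' @return object of class `forcing_spec`.
#' @export
forcing_spec <- function(years = 7, seed = 1L,
                         thermal = list(), mixing = list(), nep = list(),
                         river = list(), init = list(), atm_pco2 = 350,
                         noise = list()) {
  spec <- list(
    years = years, seed = seed,
    thermal = utils::modifyList(list(
      t_winter = 6, t_summer = 23, t_deep = 5.5, peak_doy = 220,
      sharpness = 2), thermal),
    mixing = utils::modifyList(list(
      kz_mixed = 5000, kz_deep = 0.03, sharpness = 3,
      ml_depth = data.frame(
        doy = c(1, 25, 40, 55, 70, 100, 135, 160, 225, 255, 285, 315,
                345, 365),
        depth = c(150, 250, 306, 250, 120, 60, 40, 11, 9, 14, 26, 58,
                  100, 140))),
      mixing),
    nep = utils::modifyList(list(
      photic_scale = 18, resp_shallow_scale = 8, resp_deep_scale = 150,
      areal_target = 80, ml_share = 0.5, deep_resp_fraction = 1.5,
      spring_frac = 0.45, spring_peak = 85, spring_width = 20,
      prod_start = 160, prod_length = 130,
      resp_lag = 10, resp_base = 0.3), nep),
    river = utils::modifyList(list(
      residence_years = 11, dic = 1820, bicarb_fraction = 0.96, ca = 800,
      q_amplitude = 0.3, q_peak_doy = 170, t_min = 5, t_max = 8), river),
    init = utils::modifyList(list(
      dic = 1800, tac = 1740, ca = 800, temp = 6), init),
    atm_pco2 = atm_pco2,
    noise = utils::modifyList(list(
      t_sd = 0.3, t_phi = 0.8, prod_sd = 0.08, prod_phi = 0.9), noise))
  validate_forcing_spec(structure(spec, class = "forcing_spec"))
}

#' @rdname forcing_spec
#' @param spec a forcing specification to validate.
#' @export
validate_forcing_spec <- function(spec) {
  ck <- function(ok, msg) if (!isTRUE(ok)) .config_error(msg)
  th <- spec$thermal
  ck(th$t_summer > th$t_deep, "summer surface T must exceed deep T")
  ck(th$t_winter >= th$t_deep, "winter surface T must be >= deep T")
  ck(th$sharpness > 0, "thermocline sharpness must be > 0")
  ck(spec$mixing$kz_mixed > 0 && spec$mixing$kz_deep >= 0,
     "diffusivities must be positive")
  ck(spec$nep$areal_target >= 0, "NEP areal target must be >= 0")
  ck(spec$nep$deep_resp_fraction >= 0 && spec$nep$deep_resp_fraction <= 2,
     "deep_resp_fraction out of range")
  ck(spec$river$residence_years > 0, "residence time must be > 0")
  ck(all(spec$atm_pco2 > 0), "atmospheric pCO2 must be > 0")
  ck(spec$init$dic > 0 && spec$init$ca >= 0, "initial profiles out of range")
  spec
}

# AR(1) noise series, mean 0, marginal standard deviation sd.
.ar1 <- function(n, sd, phi) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  stats::filter(e, phi, method = "recursive")[seq_len(n)]
}

# Mixed-layer depth for each day-of-year from the control points
# (periodic linear interpolation smoothed with a 15-day running mean).
.mixed_layer_doy <- function(ml) {
  doys <- seq_len(365)
  h <- stats::approx(ml$doy, ml$depth, xout = doys, rule = 2)$y
  h3 <- rep(h, 3)
  sm <- stats::filter(h3, rep(1 / 15, 15), sides = 2, circular = TRUE)
  as.numeric(sm[366:730])
}

#' Generate synthetic forcing on the model grid
#'
#' Deterministic seasonal harmonics plus small seeded AR(1) noise; the seed
#' fully determines the output (the caller's RNG state is left untouched).
#' Produces daily temperature, vertical diffusivity and NEP fields on the
#' grid, the river boundary series, the atmospheric pCO2 series and the
#' initial profiles.
#'
#' The two NEP amplitude parameters (production, respiration) are solved
#' from the two integral constraints (net 0-30 m areal NEP equals the
#' target; respiration below 30 m returns `deep_resp_fraction` of it), so
#' the noise-free annual 0-30 m NEP matches the target exactly and the
#' noisy one stays within a few percent.
#'
#' @param spec a [forcing_spec()] object.
#' @param grid a [lake_grid()] object.
#' @return object of class `forcing_series`: matrices `temp` (n x days),
#'   `kz` ((n+1) x days), `nep` (n x days), data.frame `river`, vector
#'   `atm_pco2`, list `init`, and the originating `spec`.
#' @export
generate_forcing <- function(spec, grid) {
  spec <- validate_forcing_spec(spec)
  n_days <- spec$years * 365L
  doy <- (seq_len(n_days) - 1L) %% 365L + 1L

  seed_state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit({
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, .GlobalEnv)
  })
  set.seed(spec$seed)

  th <- spec$thermal
  t_mean <- (th$t_summer + th$t_winter) / 2
  t_amp <- (th$t_summer - th$t_winter) / 2
  t_surf <- t_mean + t_amp * cos(2 * pi * (doy - th$peak_doy) / 365) +
    .ar1(n_days, spec$noise$t_sd, spec$noise$t_phi)
  t_surf <- pmax(t_surf, th$t_deep)

  h_doy <- .mixed_layer_doy(spec$mixing$ml_depth)
  h <- h_doy[doy]

  # temperature and diffusivity profiles from the mixed-layer depth
  sig <- function(z, hh) stats::plogis((hh - z) / th$sharpness)
  w_mid <- outer(grid$mids, h, function(z, hh) sig(z, hh))
  temp <- matrix(th$t_deep, grid$n, n_days) +
    sweep(w_mid, 2, t_surf - th$t_deep, `*`)
  mx <- spec$mixing
  sig_k <- function(z, hh) stats::plogis((hh - z) / mx$sharpness)
  w_edge <- outer(grid$edges, h, function(z, hh) sig_k(z, hh))
  # interpolate log10(Kz): thermocline diffusivity drops by orders of
  # magnitude over a few metres, which a linear blend cannot represent
  kz <- 10^(log10(mx$kz_deep) +
              (log10(mx$kz_mixed) - log10(mx$kz_deep)) * w_edge)

  # NEP: production, shallow (epilimnetic) and deep respiration shapes.
  # Amplitudes are solved from three integral constraints: the 0-10 m net
  # share, the net 0-30 m areal target, and the below-30 m respiratory
  # return (deep_resp_fraction of the target; > 1 reflects mineralisation
  # of river-borne organic carbon on top of the autochthonous export).
  np <- spec$nep
  dd <- seq_len(365)
  spring <- exp(-(dd - np$spring_peak)^2 / (2 * np$spring_width^2))
  summer <- pmax(0, sin(pi * (dd - np$prod_start) / np$prod_length))
  summer[dd > np$prod_start + np$prod_length] <- 0
  s_doy <- np$spring_frac * spring / sum(spring) +
    (1 - np$spring_frac) * summer / sum(summer)
  lag_shape <- function(lag) np$resp_base + (1 - np$resp_base) *
    s_doy[((seq_len(365) - 1 - lag) %% 365) + 1]
  rs_doy <- lag_shape(np$resp_lag)          # shallow respiration season
  rd_doy <- lag_shape(np$resp_lag * 2)      # deep respiration season
  zp <- exp(-grid$mids / np$photic_scale)
  zrs <- exp(-grid$mids / np$resp_shallow_scale)
  # deep respiration mineralises exported organic carbon below the
  # productive zone only
  zrd <- ifelse(grid$mids > 30, exp(-(grid$mids - 30) / np$resp_deep_scale), 0)
  target <- np$areal_target / 12 * 1000     # g C m^-2 -> mmol C m^-2 yr^-1
  band <- function(zshape, lo, hi) {
    sel <- grid$mids > lo & grid$mids <= hi
    sum(zshape[sel] * grid$dz[sel])
  }
  sp_y <- sum(s_doy); rs_y <- sum(rs_doy); rd_y <- sum(rd_doy)
  zmax <- max(grid$edges)
  m <- rbind(
    c(sp_y * band(zp, 0, 10), -rs_y * band(zrs, 0, 10),
      -rd_y * band(zrd, 0, 10)),
    c(sp_y * band(zp, 0, 30), -rs_y * band(zrs, 0, 30),
      -rd_y * band(zrd, 0, 30)),
    c(sp_y * band(zp, 30, zmax), -rs_y * band(zrs, 30, zmax),
      -rd_y * band(zrd, 30, zmax)))
  amp <- solve(m, c(np$ml_share * target, target,
                    -np$deep_resp_fraction * target))
  if (any(amp < 0)) {
    .config_error("NEP shape constraints give negative amplitudes; adjust the production/respiration depth scales")
  }
  prod_noise <- pmax(1 + .ar1(n_days, spec$noise$prod_sd, spec$noise$prod_phi),
                     0.2)
  nep <- outer(zp, amp[1] * s_doy[doy] * prod_noise) -
    outer(zrs, amp[2] * rs_doy[doy]) -
    outer(zrd, amp[3] * rd_doy[doy])

  rv <- spec$river
  q_mean <- sum(grid$volume) / (rv$residence_years * 365)
  discharge <- q_mean * (1 + rv$q_amplitude *
                           cos(2 * pi * (doy - rv$q_peak_doy) / 365))
  river <- data.frame(
    day = seq_len(n_days),
    discharge = discharge,
    temp = rv$t_min + (rv$t_max - rv$t_min) *
      (1 + cos(2 * pi * (doy - th$peak_doy) / 365)) / 2,
    dic = rep_len(rv$dic, n_days),
    tac = rep_len(rv$dic * rv$bicarb_fraction, n_days),
    ca = rep_len(rv$ca, n_days))

  structure(list(spec = spec, n_days = n_days,
                 temp = temp, kz = kz, nep = nep, river = river,
                 atm_pco2 = rep_len(spec$atm_pco2, n_days),
                 init = spec$init),
            class = "forcing_series")
}

#' Scale the alkalinity level of a forcing series
#'
#' Multiplies the river and initial-profile alkalinity by `factor`,
#' co-scaling DIC and calcium proportionally (mimicking
#' catchment-weathering covariation and keeping the carbonate system
#' solvable at low factors). Everything else is unchanged.
#'
#' @param forcing a `forcing_series` from [generate_forcing()].
#' @param factor multiplicative alkalinity factor (> 0).
#' @return modified `forcing_series`.
#' @export
perturb_alkalinity <- function(forcing, factor) {
  stopifnot(inherits(forcing, "forcing_series"), factor > 0)
  for (f in c("dic", "tac", "ca")) {
    forcing$river[[f]] <- forcing$river[[f]] * factor
    forcing$init[[f]] <- forcing$init[[f]] * factor
  }
  forcing
}

#' Write / read forcing as long-format CSV
#'
#' The on-disk interchange format: `<stem>_fields.csv` holds the time-depth
#' fields in long format (`day`, `depth`, `variable`, `value`; diffusivity
#' at layer interfaces, temperature and NEP at layer midpoints),
#' `<stem>_river.csv` the river boundary series, and `<stem>_meta.csv` the
#' initial profiles and atmospheric pCO2. Synthetic and user-supplied
#' forcing are interchangeable through this format.
#'
#' @param forcing a `forcing_series`.
#' @param stem output path stem (three CSV files are written).
#' @param grid the [lake_grid()] the forcing is defined on.
#' @return `stem`, invisibly.
#' @export
write_forcing_csv <- function(forcing, stem, grid) {
  long <- function(m, z, var) data.frame(
    day = rep(seq_len(ncol(m)), each = nrow(m)),
    depth = rep(z, ncol(m)), variable = var, value = as.vector(m))
  fields <- rbind(long(forcing$temp, grid$mids, "temp"),
                  long(forcing$kz, grid$edges, "kz"),
                  long(forcing$nep, grid$mids, "nep"))
  utils::write.csv(fields, paste0(stem, "_fields.csv"), row.names = FALSE)
  utils::write.csv(forcing$river, paste0(stem, "_river.csv"),
                   row.names = FALSE)
  meta <- data.frame(variable = c("init_dic", "init_tac", "init_ca",
                                  "init_temp", "atm_pco2"),
                     value = c(forcing$init$dic, forcing$init$tac,
                               forcing$init$ca, forcing$init$temp %||% 6,
                               forcing$atm_pco2[1]))
  utils::write.csv(meta, paste0(stem, "_meta.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(stem, grid) {
  fields <- utils::read.csv(paste0(stem, "_fields.csv"))
  river <- utils::read.csv(paste0(stem, "_river.csv"))
  meta <- utils::read.csv(paste0(stem, "_meta.csv"))
  n_days <- max(fields$day)
  pick <- function(var, nr) {
    v <- fields[fields$variable == var, ]
    matrix(v$value[order(v$day, v$depth)], nr, n_days)
  }
  mv <- function(nm) meta$value[meta$variable == nm]
  structure(list(spec = NULL, n_days = n_days,
                 temp = pick("temp", grid$n), kz = pick("kz", grid$n + 1L),
                 nep = pick("nep", grid$n), river = river,
                 atm_pco2 = rep_len(mv("atm_pco2"), n_days),
                 init = list(dic = mv("init_dic"), tac = mv("init_tac"),
                             ca = mv("init_ca"), temp = mv("init_temp"))),
            class = "forcing_series")
}

#' Day-of-year index with leap-day pooling
#'
#' Maps calendar dates onto a 365-day index: in leap years Feb 29 is pooled
#' with Feb 28 (index 59) and later days are shifted down by one, so that a
#' given index always refers to the same calendar day. Used when ingesting
#' real-date forcing or observation series.
#'
#' @param dates a `Date` vector.
#' @return integer day-of-year in 1..365.
#' @export
doy365 <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  leap <- as.integer(format(dates, "%Y")) %% 4 == 0 &
    (as.integer(format(dates, "%Y")) %% 100 != 0 |
       as.integer(format(dates, "%Y")) %% 400 == 0)
  ifelse(leap & doy >= 60, pmax(doy - 1L, 59L), doy)
}
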