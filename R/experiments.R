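# Experiment designs and diagnostics: paired enabled/muted calcite runs,
# day-of-year climatologies, seasonal and annual flux budgets, and the
# alkalinity-scaling regression.

#' Paired calcite-enabled / calcite-muted experiment
#'
#' Runs the configured simulation twice under strictly identical forcing
#' (generated once, shared): once with the calcite module enabled, once
#' muted. The default mute sets the precipitation and dissolution rates to
#' zero; `config$mute_mode = "clamp-tac"` additionally clamps the
#' alkalinity field to its initial profile after every step (the literal
#' "fixed TAC" variant).
#'
#' @param config configuration list (see [default_config()]).
#' @param forcing optional pre-generated `forcing_series`.
#' @return list with elements `cp` and `nocp` (two `experiment_result`s).
#' @export
run_paired_experiment <- function(config = default_config(), forcing = NULL) {
  config <- validate_config(config)
  if (is.null(forcing)) {
    grid <- do.call(lake_grid, config$grid)
    forcing <- generate_forcing(config$forcing, grid)
  }
  cfg_cp <- config; cfg_cp$calcite$enabled <- TRUE
  cfg_no <- config; cfg_no$calcite$enabled <- FALSE
  list(cp = run_simulation(cfg_cp, forcing),
       nocp = run_simulation(cfg_no, forcing))
}

#' Day-of-year climatology of a diagnostic
#'
#' Cross-year per-DOY mean and sample standard deviation of the
#' volume-weighted average of a stored profile variable over a depth slice
#' (default the 0-10 m surface layer). Spin-up years are excluded.
#'
#' @param result an `experiment_result` run with `store_profiles = TRUE`.
#' @param variable one of the stored profile variables (`"ph"`, `"pco2"`,
#'   `"dic"`, `"tac"`, `"omega_calcite"`, `"precip"`) or a daily surface
#'   diagnostic (`"omega_co2"`, `"air_flux"`, ...).
#' @param depth_range numeric length-2 depth slice, m (profile variables).
#' @param include_spinup include spin-up years (default FALSE).
#' @return data.frame of class `doy_climatology`: `doy`, `mean`, `sd`, `n`.
#' @export
doy_climatology <- function(result, variable, depth_range = c(0, 10),
                            include_spinup = FALSE) {
  d <- result$daily
  keep <- if (include_spinup) rep(TRUE, nrow(d)) else
    d$year > result$spinup_years
  if (sum(keep) < 2 * 365) {
    stop("climatology needs at least two analysis years", call. = FALSE)
  }
  if (!is.null(result$profiles) && variable %in% names(result$profiles)) {
    series <- depth_average(result$profiles[[variable]], result$grid,
                            depth_range)
  } else if (variable %in% names(d)) {
    series <- d[[variable]]
  } else {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  series <- series[keep]
  doy <- d$doy[keep]
  out <- data.frame(
    doy = sort(unique(doy)),
    mean = as.numeric(tapply(series, doy, mean)),
    sd = as.numeric(tapply(series, doy, stats::sd)),
    n = as.integer(tapply(series, doy, length)))
  class(out) <- c("doy_climatology", "data.frame")
  out
}

# Meteorological season of a day-of-year on the 365-day calendar.
season_of_doy <- function(doy) {
  s <- character(length(doy))
  s[doy <= 59 | doy >= 335] <- "DJF"
  s[doy >= 60 & doy <= 151] <- "MAM"
  s[doy >= 152 & doy <= 243] <- "JJA"
  s[doy >= 244 & doy <= 334] <- "SON"
  factor(s, levels = c("DJF", "MAM", "JJA", "SON"))
}

#' Seasonal and annual air-water CO2 budgets
#'
#' Integrates the surface flux over the lake surface area for each
#' meteorological season (DJF, MAM, JJA, SON; December pooled with the
#' January/February of the same model year) and converts to Gg C using
#' 12 g mol^-1. Only complete analysis years enter; annual totals equal the
#' sum of the four seasonal totals by construction.
#'
#' @param result an `experiment_result`.
#' @param include_spinup include spin-up years (default FALSE).
#' @return list of class `seasonal_budget`: `per_year` (data.frame year x
#'   season Gg C plus `annual`), `summary` (median and quartiles per season
#'   and annually).
#' @export
seasonal_budget <- function(result, include_spinup = FALSE) {
  d <- result$daily
  if (!include_spinup) d <- d[d$year > result$spinup_years, , drop = FALSE]
  complete <- names(which(table(d$year) == 365))
  d <- d[d$year %in% as.integer(complete), , drop = FALSE]
  if (!nrow(d)) stop("no complete analysis years", call. = FALSE)
  a0 <- result$grid$area_edge[1L]
  d$season <- season_of_doy(d$doy)
  ggc <- function(flux_sum) flux_sum * a0 * 12e-12   # mmol m^-2 -> Gg C
  per_year <- do.call(rbind, lapply(split(d, d$year), function(y) {
    s <- tapply(y$air_flux, y$season, sum)
    data.frame(year = y$year[1L], season = names(s),
               flux_ggc = ggc(as.numeric(s)))
  }))
  rownames(per_year) <- NULL
  annual <- stats::aggregate(flux_ggc ~ year, per_year, sum)
  names(annual)[2] <- "annual_ggc"
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  summ <- do.call(rbind, lapply(split(per_year, per_year$season),
                                function(s) data.frame(
    season = s$season[1L], q25 = qs(s$flux_ggc)[1],
    median = qs(s$flux_ggc)[2], q75 = qs(s$flux_ggc)[3])))
  summ <- rbind(summ, data.frame(season = "annual",
                                 q25 = qs(annual$annual_ggc)[1],
                                 median = qs(annual$annual_ggc)[2],
                                 q75 = qs(annual$annual_ggc)[3]))
  rownames(summ) <- NULL
  structure(list(per_year = merge(per_year, annual), summary = summ),
            class = "seasonal_budget")
}

#' @export
print.seasonal_budget <- function(x, ...) {
  cat("<seasonal_budget> air-water CO2 flux, Gg C (positive = efflux)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Ordinary least squares of omega_CO2 on alkalinity
#'
#' @param tac annual mean alkalinity, mol m^-3.
#' @param omega_co2 annual mean CO2 saturation ratio.
#' @return object of class `regression_fit`: `slope`, `intercept`, `r2`,
#'   `n`, and the underlying points.
#' @export
fit_omega_tac <- function(tac, omega_co2) {
  if (length(tac) < 2 || length(unique(tac)) < 2) {
    stop("need >= 2 distinct alkalinity values to fit", call. = FALSE)
  }
  fit <- stats::lm(omega_co2 ~ tac)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 n = length(tac),
                 points = data.frame(tac = tac, omega_co2 = omega_co2)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> omega_CO2 = %.3f TAC %+.3f (r2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Alkalinity-scaling sweep
#'
#' One paired (calcite-enabled / muted) run per alkalinity factor, scaling
#' the river and initial alkalinity (with DIC and calcium co-scaled) by the
#' given factors. For each run the annual mean surface (0-10 m) omega_CO2 is
#' regressed on the realised annual mean surface alkalinity (mol m^-3) —
#' realised, not nominal, since precipitation itself draws alkalinity down.
#'
#' @param config configuration list.
#' @param factors alkalinity multipliers (default 1/4, 1/2, 1, 2).
#' @return list of class `alkalinity_sweep`: `points` (per factor, mode:
#'   realised TAC, omega_CO2), `fit_cp`, `fit_nocp` ([fit_omega_tac()]
#'   objects using per-year annual means).
#' @export
alkalinity_sweep <- function(config = default_config(),
                             factors = c(0.25, 0.5, 1, 2)) {
  if (length(factors) < 2) stop("need >= 2 factors", call. = FALSE)
  config <- validate_config(config)
  config$store_profiles <- FALSE
  grid <- do.call(lake_grid, config$grid)
  base <- generate_forcing(config$forcing, grid)
  rows <- list(); fits <- list()
  yearly <- list(cp = list(), nocp = list())
  for (f in factors) {
    frc <- perturb_alkalinity(base, f)
    pair <- run_paired_experiment(config, frc)
    for (mode in c("cp", "nocp")) {
      an <- annual_summary(pair[[mode]])
      yearly[[mode]][[as.character(f)]] <-
        data.frame(factor = f, tac = an$tac_mol_m3, omega_co2 = an$omega_co2)
      rows[[paste(mode, f)]] <- data.frame(
        factor = f, mode = mode, tac = mean(an$tac_mol_m3),
        omega_co2 = mean(an$omega_co2))
    }
  }
  pts_cp <- do.call(rbind, yearly$cp)
  pts_no <- do.call(rbind, yearly$nocp)
  structure(list(
    points = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    fit_cp = fit_omega_tac(pts_cp$tac, pts_cp$omega_co2),
    fit_nocp = fit_omega_tac(pts_no$tac, pts_no$omega_co2),
    factors = factors),
    class = "alkalinity_sweep")
}

#' @export
print.alkalinity_sweep <- function(x, ...) {
  cat("<alkalinity_sweep>\n  calcite enabled: ")
  print(x$fit_cp)
  cat("  calcite muted:   ")
  print(x$fit_nocp)
  invisible(x)
}

#' Literature reference regressions of omega_CO2 on alkalinity
#'
#' Published reference coefficients for the annual-mean CO2 saturation
#' versus alkalinity relationship: the calcite-enabled and
#' equilibrium-chemistry-only model variants of the modelling study this
#' simulator emulates, and the fit to the multi-lake observational
#' compilation reported alongside them. Stored for comparison plots and
#' reports only — they are not fitted here.
#'
#' @return data.frame with `source`, `slope`, `intercept`, `r2` (NA where
#'   not reported).
#' @export
reference_fits <- function() {
  data.frame(
    source = c("model_cp", "model_nocp", "lake_observations"),
    slope = c(1.84, 0.42, 1.30),
    intercept = c(-0.86, 0.69, -0.60),
    r2 = c(NA, NA, 0.76))
}

#' Compare an external lake table with the reference regressions
#'
#' Fits the same OLS of annual mean omega_CO2 on alkalinity to a
#' user-supplied table of lakes (columns `lake`, `tac_mol_m3`,
#' `omega_co2`) and juxtaposes it with [reference_fits()].
#'
#' @param table data.frame with at least 3 lakes and non-degenerate
#'   alkalinity.
#' @return list with `fit` (a `regression_fit`) and `reference`.
#' @export
compare_external_lakes <- function(table) {
  need <- c("lake", "tac_mol_m3", "omega_co2")
  if (!all(need %in% names(table))) {
    stop("table must have columns lake, tac_mol_m3, omega_co2", call. = FALSE)
  }
  if (nrow(table) < 3) stop("need at least 3 lakes to fit", call. = FALSE)
  if (length(unique(table$tac_mol_m3)) < 2) {
    stop("degenerate table: all lakes have identical alkalinity", call. = FALSE)
  }
  list(fit = fit_omega_tac(table$tac_mol_m3, table$omega_co2),
       reference = reference_fits())
}

#' Relative gain in CO2 saturation from doubling alkalinity
#'
#' Reporting utility: for a linear fit omega = a TAC + b, the relative
#' change from TAC to 2 TAC is a TAC / (a TAC + b), returned in percent.
#'
#' @param fit a `regression_fit`.
#' @param tac_ref reference alkalinity, mol m^-3.
#' @return percent change.
#' @export
doubling_gain <- function(fit, tac_ref) {
  100 * fit$slope * tac_ref / (fit$slope * tac_ref + fit$intercept)
}
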