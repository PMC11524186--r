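# Run configuration: defaults, YAML ingestion, validation.

#' Default run configuration
#'
#' Returns the full nested configuration of the reference simulation: a
#' Geneva-like basin (580 km^2, 309 m hypsometric taper) on a 2-m grid,
#' synthetic monomictic forcing, calcite precipitation enabled with the
#' default module parametrisation (trigger omega > 1.5, rate
#' 2.5 mmol C m^-3 day^-1), Schmidt-scaled piston velocity gas exchange
#' (k600 = 1 m/day, exponent 2/3; set `gas$schmidt_scaling = FALSE` for a
#' constant piston velocity) and an atmospheric reference of 350 ppm. Every
#' entry can be overridden before the run, or from a YAML file via
#' [read_config()].
#'
#' Note the initial calcium profile (and the river calcium load) are not
#' observationally constrained here: they are plausibility defaults chosen
#' to be consistent with the alkalinity charge balance of a hardwater lake,
#' and should be set per site for any real application.
#'
#' @param years total simulated years (365-day model years; default 7).
#' @param spinup_years leading years excluded from analysis (default 2).
#' @param seed integer seed for the synthetic forcing noise.
#' @return nested configuration list.
#' @export
default_config <- function(years = 7, spinup_years = 2, seed = 1L) {
  list(
    years = years,
    spinup_years = spinup_years,
    seed = seed,
    store_profiles = TRUE,
    mute_mode = "rates",
    grid = list(dz = 2, max_depth = 308, surface_area = 580e6,
                hyps_max_depth = 309),
    chemistry = list(background_ionic_strength = 1e-3),
    calcite = list(enabled = TRUE, omega_threshold = 1.5, rate = 2.5,
                   settling_velocity = 1, sediment_redissolution = TRUE,
                   redissolution_timescale = 360),
    gas = list(k600 = 1.0, schmidt_scaling = TRUE, schmidt_exponent = 2 / 3,
               atm_pco2 = 350, chemical_enhancement = FALSE),
    river = list(intrusion_range = c(30, 50), intrusion_layer = NULL),
    forcing = forcing_spec(years = years, seed = seed)
  )
}

#' Read a run configuration from a YAML file
#'
#' Entries present in the file override [default_config()]; everything else
#' keeps its default. The `forcing` block is merged into the default
#' [forcing_spec()] the same way.
#'
#' @param path path to a YAML configuration file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .config_error(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  base <- default_config(years = user$years %||% 7,
                         spinup_years = user$spinup_years %||% 2,
                         seed = user$seed %||% 1L)
  validate_config(.merge_lists(base, user))
}

.merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- .merge_lists(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a configuration list
#'
#' Checks ranges and cross-field consistency; signals a condition of class
#' `lakecarb_config_error` on failure.
#'
#' @param config configuration list.
#' @return the configuration, invisibly cleaned (forcing years synced).
#' @export
validate_config <- function(config) {
  ck <- function(ok, msg) if (!isTRUE(ok)) .config_error(msg)
  ck(config$years >= 1, "years must be >= 1")
  ck(config$spinup_years >= 0 && config$spinup_years < config$years,
     "spinup_years must be in [0, years)")
  ck(config$grid$dz > 0, "grid dz must be > 0")
  ck(config$calcite$omega_threshold > 1, "omega_threshold must be > 1")
  ck(config$calcite$rate >= 0, "calcite rate must be >= 0")
  ck(config$calcite$settling_velocity >= 0, "settling velocity must be >= 0")
  ck(config$calcite$settling_velocity <= config$grid$dz,
     "settling velocity * 1 day must not exceed the layer thickness")
  ck(config$calcite$redissolution_timescale > 0,
     "redissolution timescale must be > 0")
  ck(config$gas$k600 > 0, "k600 must be > 0")
  ck(config$gas$atm_pco2 > 0, "atm_pco2 must be > 0")
  ck(config$mute_mode %in% c("rates", "clamp-tac"),
     "mute_mode must be 'rates' or 'clamp-tac'")
  config$forcing$years <- config$years
  config$forcing <- validate_forcing_spec(config$forcing)
  config
}
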