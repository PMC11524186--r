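# Tidy on-disk output for finished runs.

#' Write a run to a directory of tidy CSV files
#'
#' Emits `daily.csv` (per-day surface diagnostics and fluxes),
#' `annual.csv` (per-year budgets), `profiles.csv` (long-format time-depth
#' diagnostics, if stored), and `manifest.csv` (seed, years, an MD5 hash of
#' the full configuration, and the package version) for reproducibility.
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_csv <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$daily, file.path(dir, "daily.csv"),
                   row.names = FALSE)
  utils::write.csv(annual_summary(result, include_spinup = TRUE),
                   file.path(dir, "annual.csv"), row.names = FALSE)
  if (!is.null(result$profiles)) {
    n <- result$grid$n
    nd <- ncol(result$profiles[[1]])
    long <- do.call(rbind, lapply(names(result$profiles), function(v)
      data.frame(day = rep(seq_len(nd), each = n),
                 depth = rep(result$grid$mids, nd),
                 variable = v,
                 value = as.vector(result$profiles[[v]]))))
    utils::write.csv(long, file.path(dir, "profiles.csv"), row.names = FALSE)
  }
  manifest <- data.frame(
    key = c("seed", "years", "spinup_years", "calcite_enabled",
            "config_md5", "package_version"),
    value = c(result$config$seed, result$years, result$spinup_years,
              result$config$calcite$enabled,
              config_hash(result$config),
              as.character(utils::packageVersion("lakecarb"))))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' MD5 hash of a configuration
#'
#' Canonical serialisation-based hash used in run manifests.
#'
#' @param config configuration list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}
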