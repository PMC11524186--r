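# Vertical model grid and hypsometry.

#' Build the vertical model grid
#'
#' Uniform layers, depth positive downward, 0 at the surface. Horizontal
#' areas follow a linear-in-depth taper from the lake surface area at z = 0
#' to zero at `hyps_max_depth` (a simple cone-like basin); pass
#' `hyps_max_depth = NULL` for a uniform-area (flat-walled) column, useful
#' for analytic comparisons.
#'
#' @param dz layer thickness, m (default 2).
#' @param max_depth deepest layer edge, m (default 308; must be a multiple
#'   of `dz`).
#' @param surface_area lake surface area, m^2 (default 580 km^2).
#' @param hyps_max_depth depth at which the basin area tapers to zero, m
#'   (default 309), or NULL for a uniform column.
#' @return object of class `lake_grid`: `n` layers, `edges` (n+1 depths),
#'   `mids`, `dz` (per-layer thickness), `area_edge` (n+1 interface areas),
#'   `area_mid`, `volume` (per-layer, m^3).
#' @export
lake_grid <- function(dz = 2, max_depth = 308, surface_area = 580e6,
                      hyps_max_depth = 309) {
  stopifnot(dz > 0, max_depth > 0, surface_area > 0)
  n <- round(max_depth / dz)
  if (abs(n * dz - max_depth) > 1e-9) {
    stop("max_depth must be a multiple of dz", call. = FALSE)
  }
  edges <- seq(0, max_depth, by = dz)
  mids <- (edges[-1] + edges[-(n + 1)]) / 2
  taper <- function(z) {
    if (is.null(hyps_max_depth)) return(rep_len(1, length(z)))
    pmax(1 - z / hyps_max_depth, 0)
  }
  if (!is.null(hyps_max_depth) && hyps_max_depth < max_depth) {
    stop("hyps_max_depth must be >= max_depth", call. = FALSE)
  }
  area_edge <- surface_area * taper(edges)
  area_mid <- surface_area * taper(mids)
  structure(list(n = n, edges = edges, mids = mids, dz = rep_len(dz, n),
                 area_edge = area_edge, area_mid = area_mid,
                 volume = area_mid * dz, surface_area = surface_area),
            class = "lake_grid")
}

#' @export
print.lake_grid <- function(x, ...) {
  cat(sprintf(
    "<lake_grid> %d layers x %.3g m, surface area %.3g km^2, volume %.3g km^3\n",
    x$n, x$dz[1], x$surface_area / 1e6, sum(x$volume) / 1e9))
  invisible(x)
}

#' Volume-weighted average of a layered field over a depth range
#'
#' @param values per-layer values (vector) or a layers-by-time matrix.
#' @param grid a [lake_grid()] object.
#' @param depth_range numeric length-2, metres (default c(0, 10)).
#' @return scalar (vector input) or per-time vector (matrix input).
#' @export
depth_average <- function(values, grid, depth_range = c(0, 10)) {
  sel <- grid$mids >= depth_range[1] & grid$mids <= depth_range[2]
  if (!any(sel)) stop("depth range selects no layers", call. = FALSE)
  w <- grid$volume[sel]
  if (is.matrix(values)) {
    unname(colSums(values[sel, , drop = FALSE] * w) / sum(w))
  } else {
    sum(values[sel] * w) / sum(w)
  }
}
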