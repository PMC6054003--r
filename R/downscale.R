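#' Delta-method downscaling of monthly anomalies
#'
#' Implements the delta method: each coarse monthly anomaly layer is
#' bilinearly interpolated (cell-centre nodes, edge replication beyond the
#' outermost centres) to the fine baseline geometry and added to the
#' corresponding baseline layer. Temperature deltas are additive degC.
#' Precipitation deltas are additive mm with a floor at 0 by default, or
#' multiplicative (delta as a fraction of the baseline) with
#' `mult_precip = TRUE`.
#'
#' @param baseline fine-resolution `monthly_climate`.
#' @param anomaly coarse `monthly_climate` of deltas (its extent must cover
#'   the baseline extent).
#' @param mult_precip treat precipitation deltas as multiplicative fractions.
#' @param label label for the result (defaults to the anomaly's label).
#' @return a `monthly_climate` on the baseline geometry.
#' @export
downscale <- function(baseline, anomaly, mult_precip = FALSE, label = NULL) {
  stopifnot(inherits(baseline, "monthly_climate"),
            inherits(anomaly, "monthly_climate"))
  bd <- dim(baseline$prec)
  ## extent check: anomaly grid must cover the baseline extent
  a_lon <- anomaly$origin[1] + c(0, dim(anomaly$prec)[2] * anomaly$cell_size)
  a_lat <- anomaly$origin[2] - c(dim(anomaly$prec)[1] * anomaly$cell_size, 0)
  b_lon <- baseline$origin[1] + c(0, bd[2] * baseline$cell_size)
  b_lat <- baseline$origin[2] - c(bd[1] * baseline$cell_size, 0)
  tol <- 1e-6
  if (a_lon[1] > b_lon[1] + tol || a_lon[2] < b_lon[2] - tol ||
      a_lat[1] > b_lat[1] + tol || a_lat[2] < b_lat[2] - tol)
    stop("anomaly extent does not cover the baseline extent")

  fine_geom <- grid_raster(matrix(0, bd[1], bd[2]), baseline$origin,
                           baseline$cell_size)
  interp <- function(layer) {
    coarse <- grid_raster(layer, anomaly$origin, anomaly$cell_size)
    bilinear_to_geometry(coarse, fine_geom)$values
  }
  prec <- baseline$prec; tmin <- baseline$tmin; tmax <- baseline$tmax
  for (m in 1:12) {
    dp <- interp(anomaly$prec[, , m])
    prec[, , m] <- if (mult_precip) pmax(0, baseline$prec[, , m] * (1 + dp))
                   else pmax(0, baseline$prec[, , m] + dp)
    tmin[, , m] <- baseline$tmin[, , m] + interp(anomaly$tmin[, , m])
    tmax[, , m] <- baseline$tmax[, , m] + interp(anomaly$tmax[, , m])
  }
  monthly_climate(prec, tmin, tmax, baseline$origin, baseline$cell_size,
                  label = if (is.null(label)) anomaly$label else label)
}

#' Per-cell ensemble mean of scenario climates
#'
#' @param scenarios non-empty list of `monthly_climate` objects sharing one
#'   geometry.
#' @param label label for the mean climate.
#' @return a `monthly_climate`.
#' @export
ensemble_mean_climate <- function(scenarios, label = "ensemble_mean") {
  stopifnot(length(scenarios) >= 1L)
  ref <- scenarios[[1]]
  for (s in scenarios[-1]) {
    if (!all(dim(s$prec) == dim(ref$prec)) ||
        any(abs(s$origin - ref$origin) > 1e-9) ||
        abs(s$cell_size - ref$cell_size) > 1e-9)
      stop("geometry mismatch among scenarios")
  }
  n <- length(scenarios)
  acc <- function(var) Reduce(`+`, lapply(scenarios, `[[`, var)) / n
  monthly_climate(acc("prec"), acc("tmin"), acc("tmax"),
                  ref$origin, ref$cell_size, label = label, check = FALSE)
}
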