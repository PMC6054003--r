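#' Per-pixel ensemble uncertainty metrics
#'
#' Across a list of per-GCM yield-change fields: the ensemble mean change,
#' the sample standard deviation (n - 1 denominator), and the agreement -
#' the percentage of models predicting change in the same (majority)
#' direction, `100 x max(#negative, #non-negative) / n`, with zero counted
#' as non-negative. Agreement is bounded below by 50 % wherever all models
#' are valid.
#'
#' @param changes list (length >= 2) of `grid_raster`s of yield change
#'   (kg/ha or %), shared geometry.
#' @return an object of class `ensemble_metrics`: `mean_change`,
#'   `sd_change`, `agreement` (`grid_raster`s), and `n_models`.
#' @export
ensemble_metrics <- function(changes) {
  stopifnot(length(changes) >= 2L)
  ref <- changes[[1]]
  for (r in changes[-1]) stop_if_geometry_differs(ref, r, "change fields")
  n <- length(changes)
  arr <- vapply(changes, function(r) r$values,
                matrix(0, nrow(ref$values), ncol(ref$values)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  neg <- apply(arr < 0, c(1, 2), sum)
  agree <- 100 * pmax(neg, n - neg) / n
  agree[!is.finite(mu)] <- NA_real_
  g <- function(v) grid_raster(v, ref$origin, ref$cell_size)
  structure(list(mean_change = g(mu), sd_change = g(sdv),
                 agreement = g(agree), n_models = n),
            class = "ensemble_metrics")
}

#' @export
print.ensemble_metrics <- function(x, ...) {
  cat(sprintf("ensemble_metrics over %d models\n", x$n_models))
  cat(sprintf("  mean change %.1f; SD %.1f; agreement %.1f %% (grid means)\n",
              mean(x$mean_change$values, na.rm = TRUE),
              mean(x$sd_change$values, na.rm = TRUE),
              mean(x$agreement$values, na.rm = TRUE)))
  invisible(x)
}

#' Zonal seasonal yield-change summary
#'
#' Per administrative zone and season: the zone-mean percent yield change;
#' then per season, the percentage of zones with mean loss exceeding
#' `loss_threshold`, both over all zones and within the top-producing
#' subset of zones jointly accounting for at least 50 % of total baseline
#' production (zones sorted by production, greedy prefix).
#'
#' @param changes_pct named list (one per season) of `grid_raster`s of
#'   percent yield change.
#' @param zones `grid_raster` of integer zone ids, aligned with the change
#'   fields.
#' @param baseline_yield `grid_raster` of baseline yields (kg/ha) used to
#'   derive zonal production weights (yield x pixel count).
#' @param loss_threshold percent loss defining an affected zone
#'   (default 10).
#' @return an object of class `season_summary`: `zone_table` (zone x
#'   season mean changes with production), `season_table` (per season:
#'   mean change, % zones over threshold, % of top-production zones over
#'   threshold), and `top_zones` (ids of the 50 %-of-production subset).
#' @export
season_summary <- function(changes_pct, zones, baseline_yield,
                           loss_threshold = 10) {
  ref <- changes_pct[[1]]
  stop_if_geometry_differs(ref, zones, "change field and zones")
  stop_if_geometry_differs(ref, baseline_yield, "change field and baseline")
  zid <- as.vector(zones$values)
  base <- as.vector(baseline_yield$values)
  ids <- sort(unique(zid[is.finite(zid)]))
  prod <- vapply(ids, function(z)
    sum(base[zid == z], na.rm = TRUE), numeric(1))
  means <- vapply(changes_pct, function(r)
    vapply(ids, function(z)
      mean(as.vector(r$values)[zid == z], na.rm = TRUE), numeric(1)),
    numeric(length(ids)))
  means <- matrix(means, nrow = length(ids),
                  dimnames = list(NULL, names(changes_pct)))
  valid <- prod > 0 & apply(is.finite(means), 1L, any)
  dropped <- ids[!valid]
  if (length(dropped))
    warning("omitting ", length(dropped),
            " empty zone(s): no baseline production or no valid pixels")
  ids <- ids[valid]; prod <- prod[valid]
  means <- means[valid, , drop = FALSE]
  ord <- order(prod, decreasing = TRUE)
  cum <- cumsum(prod[ord]) / sum(prod)
  top <- ids[ord[seq_len(which(cum >= 0.5)[1])]]
  season_table <- data.frame(
    season = colnames(means),
    mean_change_pct = colMeans(means, na.rm = TRUE),
    pct_zones_loss_gt_thr = 100 * colMeans(means < -loss_threshold,
                                           na.rm = TRUE),
    pct_top_zones_loss_gt_thr = 100 *
      colMeans(means[ids %in% top, , drop = FALSE] < -loss_threshold,
               na.rm = TRUE),
    row.names = NULL)
  zone_table <- data.frame(zone = ids, production = prod, means,
                           row.names = NULL)
  structure(list(zone_table = zone_table, season_table = season_table,
                 top_zones = top, loss_threshold = loss_threshold),
            class = "season_summary")
}

#' @export
print.season_summary <- function(x, ...) {
  cat(sprintf("season_summary over %d zones (loss threshold %g %%)\n",
              nrow(x$zone_table), x$loss_threshold))
  print(x$season_table, digits = 3)
  invisible(x)
}

#' Fertilizer response ratio field
#'
#' Per-pixel ratio of unfertilized to fully fertilized (F2) yields from
#' matched simulation runs; in \[0, 1\] by the fertilizer-ordering property
#' of the emulator, `NA` where the F2 yield is 0.
#'
#' @param yield_nofert,yield_f2 yield `grid_raster`s from matched runs.
#' @return a `grid_raster` of ratios.
#' @export
fertilizer_response <- function(yield_nofert, yield_f2) {
  stop_if_geometry_differs(yield_nofert, yield_f2, "matched yield runs")
  a <- yield_nofert$values; b <- yield_f2$values
  ratio <- ifelse(is.na(b) | b == 0, NA_real_, a / b)
  grid_raster(ratio, yield_f2$origin, yield_f2$cell_size)
}
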