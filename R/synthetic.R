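#' Configuration for the synthetic study region
#'
#' Parameters of the generated inputs: a WorldClim-style fine-resolution
#' monthly climatology with a bimodal (canicula-split) wet season, a smooth
#' correlated DEM, a set of coarse pseudo-GCM monthly anomaly stacks, a patchy
#' mid-elevation growing-area mask, and a community table. The defaults
#' emulate a tropical savanna drybean region: ~1400 mm annual rainfall
#' concentrated May-October with a July-August dip, temperatures lapsing
#' 0.6 degC per 100 m from a warm lowland base.
#'
#' @param grid_shape `c(rows, cols)` of the fine grid.
#' @param cell_size fine cell edge, degrees (default 1/24 deg, i.e. 2.5').
#' @param origin NW corner `c(lon, lat)`.
#' @param n_gcms number of pseudo-GCM anomaly stacks (default 19).
#' @param seed integer master seed; everything generated is a deterministic
#'   function of it.
#' @param annual_rain_mm domain-average annual rainfall total.
#' @param canicula_depth fractional July-August rainfall reduction relative
#'   to the adjacent wet-season months, in \[0, 1\].
#' @param lapse_c_per_100m temperature lapse rate, degC per 100 m elevation.
#' @param tmax_sea_level,tmin_sea_level annual-mean lowland (0 m) maximum and
#'   minimum temperatures, degC.
#' @param dem_range elevation range `c(min, max)` in m.
#' @param coarse_factor how much coarser the anomaly grids are than the
#'   baseline grid.
#' @param warming_2020s,warming_2050s ensemble-centre temperature deltas,
#'   degC, for the two future periods.
#' @param gcm_spread_c inter-GCM standard deviation of the warming centre.
#' @param prec_delta_sd_frac inter-GCM SD of monthly precipitation deltas, as
#'   a fraction of the baseline monthly total (mixed sign).
#' @param n_communities number of communities to sample (10-20).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(40L, 40L), cell_size = 1 / 24,
                             origin = c(-87, 14), n_gcms = 19L, seed = 1L,
                             annual_rain_mm = 1400, canicula_depth = 0.5,
                             lapse_c_per_100m = 0.6,
                             tmax_sea_level = 35, tmin_sea_level = 22,
                             dem_range = c(0, 2200), coarse_factor = 5L,
                             warming_2020s = 1.0, warming_2050s = 2.0,
                             gcm_spread_c = 0.4, prec_delta_sd_frac = 0.10,
                             n_communities = 15L) {
  stopifnot(n_gcms >= 2L, annual_rain_mm > 0,
            canicula_depth >= 0, canicula_depth <= 1,
            n_communities >= 1L)
  structure(as.list(environment()), class = "synthetic_config")
}

## smooth random surface in [0,1]: coarse gaussian noise, bilinearly
## upsampled, then lightly blurred -- cheap stand-in for filtered noise
smooth_field <- function(nr, nc, knots = 6L) {
  coarse <- grid_raster(matrix(stats::rnorm(knots * knots), knots, knots),
                        origin = c(0, 1), cell_size = 1 / knots)
  fine <- grid_raster(matrix(0, nr, nc), origin = c(0, 1),
                      cell_size = 1 / max(nr, nc))
  f <- bilinear_to_geometry(coarse, fine)$values
  f <- f + matrix(stats::rnorm(nr * nc, sd = 0.08), nr, nc)
  ## 3x3 box blur to keep local texture smooth
  pad <- rbind(f[1, ], f, f[nr, ]); pad <- cbind(pad[, 1], pad, pad[, nc])
  b <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    b <- b + pad[dr + seq_len(nr), dc + seq_len(nc)]
  b <- b / 9
  rng <- range(b)
  if (diff(rng) == 0) return(matrix(0.5, nr, nc))
  (b - rng[1]) / diff(rng)
}

## seasonal rainfall shape: bimodal May-Oct wet season, canicula dip in
## Jul-Aug; returns monthly fractions summing to 1
rain_month_weights <- function(canicula_depth) {
  w <- c(0.01, 0.01, 0.02, 0.04, 0.13, 0.16, 0.16, 0.16, 0.15, 0.11,
         0.03, 0.02)
  w[7:8] <- w[7:8] * (1 - canicula_depth)
  w / sum(w)
}

## monthly temperature seasonal cycle anomalies (degC) about the annual mean;
## warmest just before the rains, mild wet-season depression
temp_season_cycle <- c(-0.6, 0.1, 1.1, 1.9, 1.4, 0.2, 0.3, 0.4, -0.2, -0.9,
                       -1.6, -2.1)

#' Generate the baseline climatology and DEM
#'
#' A smooth DEM spanning `cfg$dem_range`; monthly tmin/tmax that lapse with
#' elevation and follow a mild seasonal cycle; monthly rainfall following a
#' bimodal May-October wet season with a July-August canicula dip, modulated
#' by a smooth spatial wetness field and a weak orographic enhancement.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `climate` (a `monthly_climate`) and `dem` (a
#'   `grid_raster`, metres).
#' @export
make_baseline_climate <- function(cfg) {
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  with_seed(cfg$seed, {
    dem_f <- smooth_field(nr, nc, knots = 5L)
    wet_f <- smooth_field(nr, nc, knots = 7L)
    dem <- cfg$dem_range[1] + dem_f * diff(cfg$dem_range)
    lapse <- cfg$lapse_c_per_100m * dem / 100
    w <- rain_month_weights(cfg$canicula_depth)
    ## wetness modulation 0.7-1.3 plus ~15% orographic enhancement at the top
    pmod <- (0.7 + 0.6 * wet_f) * (1 + 0.15 * dem / max(cfg$dem_range[2], 1))
    prec <- array(0, c(nr, nc, 12))
    tmin <- array(0, c(nr, nc, 12))
    tmax <- array(0, c(nr, nc, 12))
    for (m in 1:12) {
      prec[, , m] <- cfg$annual_rain_mm * w[m] * pmod
      tmax[, , m] <- cfg$tmax_sea_level + temp_season_cycle[m] - lapse
      tmin[, , m] <- cfg$tmin_sea_level + 0.6 * temp_season_cycle[m] - lapse
    }
    list(climate = monthly_climate(prec, tmin, tmax, cfg$origin,
                                   cfg$cell_size, label = "baseline"),
         dem = grid_raster(dem, cfg$origin, cfg$cell_size))
  })
}

#' Generate coarse pseudo-GCM monthly anomaly stacks
#'
#' Each pseudo-GCM contributes a coarse-resolution `monthly_climate` of
#' deltas: temperature deltas drawn around the period's warming centre with
#' inter-GCM spread and smooth within-grid structure; precipitation deltas of
#' mixed sign, proportional in scale to the baseline monthly totals.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @param period `"2020s"` or `"2050s"`.
#' @return list of `cfg$n_gcms` anomaly stacks (class `monthly_climate`,
#'   built with `check = FALSE` since deltas may be negative).
#' @export
make_gcm_anomalies <- function(cfg, period = c("2020s", "2050s")) {
  period <- match.arg(period)
  centre <- if (period == "2020s") cfg$warming_2020s else cfg$warming_2050s
  f <- cfg$coarse_factor
  nr <- max(1L, cfg$grid_shape[1] %/% f)
  nc <- max(1L, cfg$grid_shape[2] %/% f)
  ## coarse geometry covering the fine extent
  cell <- cfg$cell_size * cfg$grid_shape[1] / nr
  w <- rain_month_weights(cfg$canicula_depth)
  pseed <- if (period == "2020s") 1L else 2L
  lapply(seq_len(cfg$n_gcms), function(g) {
    with_seed(cfg$seed * 1009L + pseed * 131L + g, {
      ## every inter-GCM difference scales with the spread parameters, so
      ## zero spread collapses the ensemble to identical stacks
      dT <- centre + stats::rnorm(1, sd = cfg$gcm_spread_c)
      prec <- array(0, c(nr, nc, 12))
      tmin <- array(0, c(nr, nc, 12))
      tmax <- array(0, c(nr, nc, 12))
      tpat <- smooth_field(nr, nc, knots = max(2L, nr %/% 2L))
      ppat <- smooth_field(nr, nc, knots = max(2L, nr %/% 2L))
      for (m in 1:12) {
        tmax[, , m] <- dT + 0.75 * cfg$gcm_spread_c * (tpat - 0.5) +
          stats::rnorm(1, sd = 0.25 * cfg$gcm_spread_c)
        tmin[, , m] <- dT + 0.6 * cfg$gcm_spread_c * (tpat - 0.5) +
          stats::rnorm(1, sd = 0.25 * cfg$gcm_spread_c)
        base_m <- cfg$annual_rain_mm * w[m]
        prec[, , m] <- base_m * cfg$prec_delta_sd_frac *
          (2 * (ppat - 0.5) + stats::rnorm(1, sd = 0.5))
      }
      ## tmax warms at least as much as tmin so tmax-tmin never shrinks
      ## below zero after delta addition
      d <- tmax - tmin
      tmax <- tmax + pmax(0, -d)
      monthly_climate(prec, tmin, tmax, cfg$origin, cell,
                      label = sprintf("gcm%02d_%s", g, period),
                      check = FALSE)
    })
  })
}

#' Generate the growing-area mask and community table
#'
#' The growing area is the intersection of a mid-elevation band (400-2000 m,
#' the Mesoamerican drybean belt) with a smooth suitability field, giving a
#' patchy binary mask. Communities are sampled from mask cells, with
#' elevations read off the DEM at their cells.
#'
#' @param cfg a [synthetic_config()].
#' @param dem the DEM `grid_raster` from [make_baseline_climate()].
#' @return list with `atlas` (binary `grid_raster` mask) and `communities`
#'   (data.frame: name, lon, lat, elevation_m, row, col).
#' @export
make_atlas_and_communities <- function(cfg, dem) {
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  with_seed(cfg$seed + 7L, {
    suit <- smooth_field(nr, nc, knots = 6L)
    band <- dem$values >= 400 & dem$values <= 2000
    mask <- band & suit > stats::quantile(suit[band], 0.35)
    if (!any(mask)) stop("empty feasible region: no mask cells in the ",
                         "400-2000 m band")
    idx <- which(mask)
    n <- min(cfg$n_communities, length(idx))
    pick <- sample(idx, n)
    cc <- cell_centers(dem)
    rows <- ((pick - 1L) %% nr) + 1L
    cols <- ((pick - 1L) %/% nr) + 1L
    communities <- data.frame(
      name = sprintf("Community%02d", seq_len(n)),
      lon = cc$lon[cols], lat = cc$lat[rows],
      elevation_m = dem$values[pick],
      row = rows, col = cols, stringsAsFactors = FALSE)
    list(atlas = grid_raster(mask * 1, dem$origin, dem$cell_size),
         communities = communities)
  })
}

#' Synthetic municipality zones
#'
#' Partitions the grid into rectangular blocks standing in for administrative
#' zones, for zonal yield-change summaries.
#'
#' @param template a `grid_raster` supplying the geometry.
#' @param block block edge in cells (default 5).
#' @return a `grid_raster` of integer zone ids.
#' @export
make_zones <- function(template, block = 5L) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  ri <- ceiling(seq_len(nr) / block); ci <- ceiling(seq_len(nc) / block)
  z <- outer(ri, ci, function(a, b) (b - 1L) * max(ri) + a)
  grid_raster(z, template$origin, template$cell_size)
}

#' Write the synthetic input set to a directory
#'
#' ESRI ASCII grids for the DEM, atlas mask and the 36 baseline layers, plus
#' `communities.csv`.
#'
#' @param cfg a [synthetic_config()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- make_baseline_climate(cfg)
  atlas <- make_atlas_and_communities(cfg, base$dem)
  write_raster(base$dem, file.path(dir, "dem.asc"))
  write_raster(atlas$atlas, file.path(dir, "atlas_mask.asc"))
  for (var in c("prec", "tmin", "tmax"))
    for (m in 1:12)
      write_raster(monthly_layer(base$climate, var, m),
                   file.path(dir, sprintf("%s_%02d.asc", var, m)))
  utils::write.csv(atlas$communities[c("name", "lon", "lat", "elevation_m")],
                   file.path(dir, "communities.csv"), row.names = FALSE)
  invisible(dir)
}
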