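#' Run the full high-impact-spot pipeline on synthetic inputs
#'
#' Chains every stage of the assessment on a generated study region:
#' \enumerate{
#'   \item generate the baseline climatology, DEM, growing-area atlas and
#'     communities ([make_baseline_climate()], [make_atlas_and_communities()]);
#'   \item generate coarse pseudo-GCM monthly anomalies and downscale each
#'     to the baseline grid with the delta method ([make_gcm_anomalies()],
#'     [downscale()]);
#'   \item simulate the eight-treatment factorial over all atlas pixels for
#'     the baseline and the GCM-ensemble-mean climate ([run_grid()]),
#'     averaging the requested replicate years of generated daily weather;
#'   \item compute the yield change, scale it robustly (or with the local
#'     Getis-Ord statistic) and classify hotspots, adaptation spots and
#'     pressure spots ([yield_change()], [robust_rms_scale()],
#'     [classify_spots()]);
#'   \item select study sites near communities inside the negative spots
#'     ([select_study_sites()]);
#'   \item run all pseudo-GCMs at the site pixels and compute ensemble
#'     uncertainty metrics ([run_cells()], [ensemble_metrics()]);
#'   \item summarise seasonal changes by synthetic municipality zones
#'     ([season_summary()]) and the fertilizer response at the sites
#'     ([fertilizer_response()]).
#' }
#'
#' @param cfg a [synthetic_config()]; its `seed` drives all randomness.
#' @param period future period, `"2020s"` or `"2050s"`.
#' @param n_years replicate weather years per pixel (default 20).
#' @param seasons named list of season windows (default all three).
#' @param method classification field: `"robust_z"` or `"getis_ord"`.
#' @param band_km Getis-Ord distance band, km.
#' @param n_sites maximum number of study sites.
#' @param max_site_pixels cap on site pixels carried into the per-GCM
#'   uncertainty runs (keeps the ensemble stage proportionate).
#' @param gcm_subset optional integer vector of pseudo-GCM indices to use
#'   in the site-level uncertainty stage (default all).
#' @param verbose print per-stage progress.
#' @return a list with the stage outputs: `inputs` (climate, dem, atlas,
#'   communities, zones), `scenarios` (per-GCM downscaled climates and
#'   their ensemble mean), `yields` (per season/treatment, baseline and
#'   future), `change` (primera `yield_change`), `z`, `classification`,
#'   `site_pixels`, `ensemble` (`ensemble_metrics` on site-pixel changes),
#'   `seasons` (`season_summary`), `fertilizer_ratio`, and `config`.
#' @export
run_pipeline <- function(cfg = synthetic_config(), period = "2050s",
                         n_years = 20L, seasons = season_windows(),
                         method = c("robust_z", "getis_ord"), band_km = 15,
                         n_sites = 15L, max_site_pixels = 200L,
                         gcm_subset = NULL, verbose = TRUE) {
  method <- match.arg(method)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[1/7] generating synthetic inputs (%d x %d grid, %d pseudo-GCMs)",
      cfg$grid_shape[1], cfg$grid_shape[2], cfg$n_gcms)
  base <- make_baseline_climate(cfg)
  atlas <- make_atlas_and_communities(cfg, base$dem)
  zones <- make_zones(base$dem)

  say("[2/7] delta-downscaling %d pseudo-GCM anomaly stacks (%s)",
      cfg$n_gcms, period)
  anomalies <- make_gcm_anomalies(cfg, period)
  scenarios <- lapply(anomalies, function(a) downscale(base$climate, a))
  ens_climate <- ensemble_mean_climate(scenarios)

  say("[3/7] simulating the 8-treatment factorial over %d pixels (x2 scenarios, %d years)",
      prod(cfg$grid_shape), n_years)
  ## the whole region is simulated; the atlas only gates the hotspot /
  ## adaptation categories, so pressure spots outside it are still mapped
  treatments <- treatment_design()
  y_base <- run_grid(base$climate, seasons, treatments, n_years,
                     seed = cfg$seed)
  y_fut <- run_grid(ens_climate, seasons, treatments, n_years,
                    seed = cfg$seed)

  say("[4/7] classifying high-impact spots (method %s)", method)
  change <- yield_change(y_fut$primera, y_base$primera)
  z <- if (method == "getis_ord") {
    getis_ord_local(change$delta, d_km = band_km)
  } else {
    rz <- robust_rms_scale(as.vector(change$delta$values))
    grid_raster(matrix(rz$z, nrow(change$delta$values),
                       ncol(change$delta$values)),
                change$delta$origin, change$delta$cell_size)
  }
  classification <- classify_spots(z, atlas$atlas, method = method)

  say("[5/7] selecting study sites")
  site_px <- select_study_sites(atlas$communities, classification,
                                atlas$atlas, base$dem, n_sites = n_sites)
  if (nrow(site_px) > max_site_pixels)
    site_px <- site_px[seq_len(max_site_pixels), , drop = FALSE]

  gcms <- if (is.null(gcm_subset)) seq_along(scenarios) else gcm_subset
  say("[6/7] per-GCM uncertainty runs at %d site pixels x %d GCMs",
      nrow(site_px), length(gcms))
  ensemble <- NULL
  fert_ratio <- NULL
  if (nrow(site_px) > 0L) {
    cells <- site_px[c("row", "col")]
    prim <- seasons["primera"]
    base_site <- run_cells(base$climate, cells, prim, treatments, n_years,
                           seed = cfg$seed)$primera
    base_mean <- rowMeans(base_site)
    gcm_changes <- if (length(gcms) < 2L) NULL else lapply(gcms, function(g) {
      fut <- run_cells(scenarios[[g]], cells, prim, treatments, n_years,
                       seed = cfg$seed)$primera
      d <- nrow(base$dem$values); nc <- ncol(base$dem$values)
      v <- matrix(NA_real_, d, nc)
      v[cbind(cells$row, cells$col)] <- rowMeans(fut) - base_mean
      grid_raster(v, base$dem$origin, base$dem$cell_size)
    })
    if (!is.null(gcm_changes)) ensemble <- ensemble_metrics(gcm_changes)

    ## fertilizer response: matched F2 vs fertilization-disabled site runs
    tr_f2 <- treatment_design("F2")
    tr_no <- treatment_design("none")
    f2 <- rowMeans(run_cells(base$climate, cells, prim, tr_f2, n_years,
                             seed = cfg$seed)$primera)
    no <- rowMeans(run_cells(base$climate, cells, prim, tr_no, n_years,
                             seed = cfg$seed)$primera)
    d <- nrow(base$dem$values); ncd <- ncol(base$dem$values)
    gf <- function(x) {
      v <- matrix(NA_real_, d, ncd)
      v[cbind(cells$row, cells$col)] <- x
      grid_raster(v, base$dem$origin, base$dem$cell_size)
    }
    fert_ratio <- fertilizer_response(gf(no), gf(f2))
  }

  say("[7/7] zonal seasonal summary")
  changes_pct <- lapply(names(seasons), function(s)
    yield_change(y_fut[[s]], y_base[[s]])$relative)
  names(changes_pct) <- names(seasons)
  seas <- season_summary(changes_pct, zones,
                         yield_change(y_fut$primera,
                                      y_base$primera)$mean_baseline)

  list(inputs = list(climate = base$climate, dem = base$dem,
                     atlas = atlas$atlas, communities = atlas$communities,
                     zones = zones),
       scenarios = list(gcms = scenarios, ensemble_mean = ens_climate),
       yields = list(baseline = y_base, future = y_fut),
       change = change, z = z, classification = classification,
       site_pixels = site_px, ensemble = ensemble, seasons = seas,
       fertilizer_ratio = fert_ratio, config = cfg, period = period,
       n_years = n_years)
}
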