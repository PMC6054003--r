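#' Yield change between future and baseline simulations
#'
#' Averages the treatment yield surfaces per scenario, then takes the
#' per-pixel difference (future - baseline, kg/ha) and the percent change
#' relative to baseline (undefined where the baseline is 0).
#'
#' @param future,baseline named lists of yield `grid_raster`s, one per
#'   treatment; the two lists must share treatment ids and geometry.
#' @return an object of class `yield_change`: list with `delta` and
#'   `relative` (`grid_raster`s), and the per-scenario treatment means
#'   `mean_future`, `mean_baseline`.
#' @export
yield_change <- function(future, baseline) {
  if (!setequal(names(future), names(baseline)) ||
      length(future) != length(baseline))
    stop("treatment sets differ between future and baseline")
  baseline <- baseline[names(future)]
  ref <- future[[1]]
  for (r in c(future, baseline)) stop_if_geometry_differs(ref, r)
  avg <- function(lst) Reduce(`+`, lapply(lst, `[[`, "values")) / length(lst)
  mf <- avg(future); mb <- avg(baseline)
  delta <- mf - mb
  rel <- ifelse(is.na(mb) | mb == 0, NA_real_, 100 * delta / mb)
  g <- function(v) grid_raster(v, ref$origin, ref$cell_size)
  structure(list(delta = g(delta), relative = g(rel),
                 mean_future = g(mf), mean_baseline = g(mb)),
            class = "yield_change")
}

#' @export
print.yield_change <- function(x, ...) {
  d <- x$delta$values; r <- x$relative$values
  cat("yield_change (future - baseline, mean over treatments)\n")
  cat(sprintf("  delta: mean %.1f kg/ha; relative: mean %.1f %% (%d valid pixels)\n",
              mean(d, na.rm = TRUE), mean(r, na.rm = TRUE),
              sum(is.finite(d))))
  invisible(x)
}

#' Robust root-mean-square scaling
#'
#' Iteratively scales a sample by its root-mean-square deviation while
#' excluding gross outliers: deviations are taken from the mean of the
#' currently included points, the RMS of the included deviations is the
#' scale, points deviating more than `k` scales are excluded, and the
#' procedure repeats until the included set is stable (at most `max_iter`
#' passes). All points - including excluded ones - are returned scaled by
#' the final centre and scale.
#'
#' @param x numeric values (NAs allowed, at least 3 valid values required).
#' @param k exclusion multiplier (default 3).
#' @param max_iter iteration cap (default 20).
#' @return list with `z` (same length as `x`), `center`, `scale`,
#'   `iterations`, and logical `included` for the valid entries.
#' @export
robust_rms_scale <- function(x, k = 3, max_iter = 20L) {
  ok <- is.finite(x)
  if (sum(ok) < 3L) stop("need at least 3 valid values")
  v <- x[ok]
  if (max(v) == min(v)) stop("degenerate input: all values equal")
  inc <- rep(TRUE, length(v))
  it <- 0L
  repeat {
    it <- it + 1L
    mu <- mean(v[inc])
    s <- sqrt(mean((v[inc] - mu)^2))
    if (s == 0) stop("degenerate input: included values all equal")
    keep <- abs(v - mu) <= k * s
    if (identical(keep, inc) || it >= max_iter) { inc <- keep; break }
    inc <- keep
  }
  z <- rep(NA_real_, length(x))
  z[ok] <- (v - mu) / s
  list(z = z, center = mu, scale = s, iterations = it, included = inc)
}

#' Local Getis-Ord Gi* statistic on a raster
#'
#' Standardised local statistic of spatial association with binary weights
#' within a great-circle distance band, including the focal cell (the
#' starred form):
#' `Gi* = (sum_j w_ij x_j - xbar W_i) / (S sqrt((n W_i - W_i^2)/(n - 1)))`
#' where `W_i` is the number of neighbours (self included), `n` the number
#' of valid cells, `xbar` and `S` the global mean and population SD.
#'
#' @param r a `grid_raster`.
#' @param d_km distance band in km (default 15).
#' @return a `grid_raster` of Gi* z-scores; cells with no neighbour in the
#'   band (impossible with self-inclusion, but kept for generality) or a
#'   zero denominator get `NA`/0 respectively.
#' @export
getis_ord_local <- function(r, d_km = 15) {
  v <- as.vector(r$values)
  ok <- which(is.finite(v))
  n <- length(ok)
  if (n < 2L) stop("need at least 2 valid cells")
  nr <- nrow(r$values)
  cc <- cell_centers(r)
  lon <- cc$lon[((ok - 1L) %/% nr) + 1L]
  lat <- cc$lat[((ok - 1L) %% nr) + 1L]
  x <- v[ok]
  xbar <- mean(x)
  S <- sqrt(mean(x^2) - xbar^2)
  z <- rep(NA_real_, n)
  pts <- cbind(lon, lat)
  for (i in seq_len(n)) {
    d <- haversine_km(pts, pts[i, ])
    nb <- d <= d_km
    W <- sum(nb)
    denom <- S * sqrt((n * W - W^2) / (n - 1))
    num <- sum(x[nb]) - xbar * W
    z[i] <- if (denom > 0) num / denom else 0
  }
  out <- rep(NA_real_, length(v))
  out[ok] <- z
  grid_raster(matrix(out, nrow(r$values), ncol(r$values)),
              r$origin, r$cell_size)
}

#' Classify pixels into high-impact spot categories
#'
#' Three categories on the scaled deviation field z: hotspots (z <= -2,
#' severe projected yield loss - about the 95 % two-sided normal band),
#' adaptation spots (-2 < z <= -1, moderate loss - the 68 % band), and
#' pressure spots (z >= +1, projected gains). Hotspots and adaptation spots
#' are reported only within the current growing area (atlas mask); pressure
#' spots are mapped everywhere, since they typically lie outside it.
#'
#' @param z `grid_raster` of z-values (robust-scaled deviations or Gi*).
#' @param atlas binary growing-area `grid_raster`, or `NULL` to classify
#'   everywhere.
#' @param method label recorded in the result (`"robust_z"` or
#'   `"getis_ord"`).
#' @return an object of class `spot_classification`: `category` (a
#'   `grid_raster` coded 0 none, 1 hotspot, 2 adaptation, 3 pressure), `z`,
#'   `method`, and `levels`.
#' @export
classify_spots <- function(z, atlas = NULL, method = "robust_z") {
  zv <- z$values
  cat_ <- matrix(NA_real_, nrow(zv), ncol(zv))
  ok <- is.finite(zv)
  cat_[ok] <- 0
  in_atlas <- if (is.null(atlas)) ok else {
    stop_if_geometry_differs(z, atlas, "z field and atlas")
    ok & !is.na(atlas$values) & atlas$values == 1
  }
  cat_[in_atlas & zv <= -2] <- 1                     # hotspot
  cat_[in_atlas & zv > -2 & zv <= -1] <- 2           # adaptation
  cat_[ok & zv >= 1] <- 3                            # pressure
  structure(list(category = grid_raster(cat_, z$origin, z$cell_size),
                 z = z, method = method,
                 levels = c("none", "hotspot", "adaptation", "pressure")),
            class = "spot_classification")
}

#' @export
print.spot_classification <- function(x, ...) {
  v <- x$category$values
  counts <- vapply(0:3, function(k) sum(v == k, na.rm = TRUE), integer(1))
  cat(sprintf("spot_classification (method %s)\n", x$method))
  cat(sprintf("  none %d | hotspot %d | adaptation %d | pressure %d\n",
              counts[1], counts[2], counts[3], counts[4]))
  invisible(x)
}

#' Category counts of a spot classification
#'
#' @param classification a [classify_spots()] result.
#' @return named integer vector over the four categories.
#' @export
spot_counts <- function(classification) {
  v <- classification$category$values
  counts <- vapply(0:3, function(k) sum(v == k, na.rm = TRUE), integer(1))
  names(counts) <- classification$levels
  counts
}

#' Kernel-density growing-area mask from presence points
#'
#' Gaussian kernel density of presence points evaluated at cell centres
#' (distances in km), thresholded at a fraction of the maximum density.
#' The default bandwidth is Silverman's rule of thumb applied to the point
#' dispersion in km.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param template `grid_raster` supplying the output geometry.
#' @param bandwidth_km kernel SD in km; `NULL` for Silverman's rule.
#' @param threshold mask cells with density >= `threshold` x max density.
#' @return list with `mask` (binary `grid_raster`), `density`
#'   (`grid_raster`), `bandwidth_km`.
#' @export
kernel_density_mask <- function(points, template, bandwidth_km = NULL,
                                threshold = 0.1) {
  stopifnot(nrow(points) >= 1L)
  if (!is.null(bandwidth_km) && bandwidth_km <= 0)
    stop("bandwidth must be positive")
  if (is.null(bandwidth_km)) {
    km_per_deg <- 111.19
    xs <- points$lon * km_per_deg * cos(mean(points$lat) * pi / 180)
    ys <- points$lat * km_per_deg
    sd_km <- sqrt((stats::var(xs) + stats::var(ys)) / 2)
    if (!is.finite(sd_km) || sd_km == 0) sd_km <- 5
    bandwidth_km <- 1.06 * sd_km * nrow(points)^(-1 / 5)
  }
  nr <- nrow(template$values); nc <- ncol(template$values)
  dens <- matrix(0, nr, nc)
  for (p in seq_len(nrow(points))) {
    d <- distance_field_km(template, points$lon[p], points$lat[p])
    dens <- dens + exp(-d^2 / (2 * bandwidth_km^2))
  }
  mask <- (dens >= threshold * max(dens)) * 1
  list(mask = grid_raster(mask, template$origin, template$cell_size),
       density = grid_raster(dens, template$origin, template$cell_size),
       bandwidth_km = bandwidth_km)
}

#' Select study pixels around a community
#'
#' Pixels passing the triple filter: great-circle distance to the community
#' at most `max_km` (default 15 km), inside the growing-area mask, and
#' elevation within `max_elev_diff` (default 100 m) of the community's
#' elevation. All comparisons inclusive.
#'
#' @param community one-row data.frame or list with `lon`, `lat`,
#'   `elevation_m`.
#' @param atlas binary growing-area `grid_raster`.
#' @param dem elevation `grid_raster`, metres.
#' @param max_km,max_elev_diff filter radii.
#' @return data.frame of selected pixels (`row`, `col`, `lon`, `lat`,
#'   `elevation_m`, `dist_km`); empty (with a warning) when nothing
#'   qualifies.
#' @export
select_site_pixels <- function(community, atlas, dem, max_km = 15,
                               max_elev_diff = 100) {
  stop_if_geometry_differs(atlas, dem, "atlas and DEM")
  d <- distance_field_km(atlas, community$lon, community$lat)
  sel <- which(d <= max_km &
                 !is.na(atlas$values) & atlas$values == 1 &
                 abs(dem$values - community$elevation_m) <= max_elev_diff)
  nr <- nrow(atlas$values)
  cc <- cell_centers(atlas)
  rows <- ((sel - 1L) %% nr) + 1L
  cols <- ((sel - 1L) %/% nr) + 1L
  out <- data.frame(row = rows, col = cols,
                    lon = cc$lon[cols], lat = cc$lat[rows],
                    elevation_m = dem$values[sel], dist_km = d[sel])
  if (nrow(out) == 0L)
    warning("no pixels qualify around community at (",
            community$lon, ", ", community$lat, ")")
  out
}

#' Select study sites inside hot/adaptation spots
#'
#' Keeps the communities whose cell falls in a hotspot or adaptation spot,
#' up to `n_sites`, and gathers each one's qualifying pixels with
#' [select_site_pixels()].
#'
#' @param communities data.frame with `name`, `lon`, `lat`, `elevation_m`,
#'   `row`, `col`.
#' @param classification a [classify_spots()] result.
#' @param atlas,dem as in [select_site_pixels()].
#' @param n_sites maximum number of sites (default 15).
#' @return data.frame of site pixels with a `site` column, plus attribute
#'   `sites` (the selected community rows with their category).
#' @export
select_study_sites <- function(communities, classification, atlas, dem,
                               n_sites = 15L) {
  catv <- classification$category$values
  cat_at <- catv[cbind(communities$row, communities$col)]
  keep <- which(cat_at %in% c(1, 2))
  if (length(keep) == 0L) {
    ## fall back to the most negative-z communities so downstream site
    ## analyses still run on weak-signal fixtures
    zc <- classification$z$values[cbind(communities$row, communities$col)]
    keep <- order(zc)[seq_len(min(n_sites, nrow(communities)))]
  }
  keep <- keep[seq_len(min(n_sites, length(keep)))]
  sites <- communities[keep, , drop = FALSE]
  sites$category <- classification$levels[cat_at[keep] + 1]
  px <- lapply(seq_len(nrow(sites)), function(i) {
    p <- select_site_pixels(sites[i, ], atlas, dem)
    if (nrow(p)) p$site <- sites$name[i]
    p
  })
  out <- do.call(rbind, px[vapply(px, nrow, integer(1)) > 0])
  if (is.null(out))
    out <- data.frame(row = integer(), col = integer(), lon = numeric(),
                      lat = numeric(), elevation_m = numeric(),
                      dist_km = numeric(), site = character())
  attr(out, "sites") <- sites
  out
}
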