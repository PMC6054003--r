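#' Monthly climatology stack
#'
#' Thirty-six co-registered layers for one scenario: monthly total
#' precipitation (mm), and mean monthly minimum and maximum temperature
#' (deg C), each as a rows x cols x 12 array sharing one geometry.
#'
#' @param prec,tmin,tmax numeric arrays `c(rows, cols, 12)`.
#' @param origin NW-corner `c(lon, lat)`, degrees.
#' @param cell_size cell edge, degrees.
#' @param label scenario label, e.g. `"baseline"` or `"gcm03_2050s"`.
#' @param check validate invariants (tmax >= tmin, prec >= 0); disable for
#'   anomaly stacks, where negative "precipitation" deltas are legitimate.
#' @return an object of class `monthly_climate`.
#' @export
monthly_climate <- function(prec, tmin, tmax, origin, cell_size,
                            label = "baseline", check = TRUE) {
  dims <- dim(prec)
  stopifnot(length(dims) == 3L, dims[3] == 12L,
            identical(dim(tmin), dims), identical(dim(tmax), dims))
  if (check) {
    if (any(prec < 0, na.rm = TRUE)) stop("monthly precipitation < 0")
    if (any(tmax < tmin, na.rm = TRUE)) stop("tmax < tmin in some cell")
  }
  structure(list(prec = prec, tmin = tmin, tmax = tmax,
                 origin = as.numeric(origin), cell_size = as.numeric(cell_size),
                 nodata = -9999, label = label),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  d <- dim(x$prec)
  cat(sprintf("monthly_climate '%s': %d x %d cells, cell %.6g deg\n",
              x$label, d[1], d[2], x$cell_size))
  cat(sprintf("  annual prec %.0f mm (grid mean); tmin %.1f, tmax %.1f degC\n",
              mean(apply(x$prec, c(1, 2), sum), na.rm = TRUE),
              mean(x$tmin, na.rm = TRUE), mean(x$tmax, na.rm = TRUE)))
  invisible(x)
}

#' Extract one monthly layer as a raster
#'
#' @param mc a `monthly_climate`.
#' @param var one of `"prec"`, `"tmin"`, `"tmax"`.
#' @param month 1-12.
#' @return a `grid_raster`.
#' @export
monthly_layer <- function(mc, var = c("prec", "tmin", "tmax"), month) {
  var <- match.arg(var)
  grid_raster(mc[[var]][, , month], mc$origin, mc$cell_size,
              nodata = mc$nodata)
}

#' Monthly climate values at one cell
#'
#' @param mc a `monthly_climate`.
#' @param row,col cell indices.
#' @return list with numeric vectors `prec`, `tmin`, `tmax` (length 12).
#' @export
climate_at_cell <- function(mc, row, col) {
  list(prec = mc$prec[row, col, ], tmin = mc$tmin[row, col, ],
       tmax = mc$tmax[row, col, ])
}

days_in_month <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

## month index of each day of a 365-day year
month_of_doy <- rep.int(1:12, days_in_month)

## run expr with a private RNG stream, restoring the caller's seed
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
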