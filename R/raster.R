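#' Georeferenced grid raster
#'
#' Minimal in-memory raster: a numeric matrix with rows ordered north to
#' south and columns west to east, an origin at the north-west corner of the
#' north-west cell, a square cell size in decimal degrees, and a nodata
#' sentinel used only at the file boundary (missing cells are `NA`
#' internally). Coordinates are geographic lon/lat (WGS84 assumed); cell
#' registration is cell-centre for all point queries.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param origin numeric length-2, `c(lon, lat)` of the NW corner in degrees.
#' @param cell_size cell edge in decimal degrees (> 0), square cells.
#' @param nodata sentinel written to / read from files (default -9999).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin, cell_size, nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(length(origin) == 2L, is.finite(origin[1]), is.finite(origin[2]))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata,
         crs = "+proj=longlat +datum=WGS84"),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("grid_raster: %d rows x %d cols, cell %.6g deg\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  NW corner: lon %.4f, lat %.4f\n", x$origin[1], x$origin[2]))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d valid, %d NA)\n",
                min(v[ok]), mean(v[ok]), max(v[ok]), sum(ok), sum(!ok)))
  else cat("  values: all NA\n")
  invisible(x)
}

#' @export
plot.grid_raster <- function(x, main = "", ...) {
  v <- x$values
  nr <- nrow(v); nc <- ncol(v)
  xs <- x$origin[1] + (seq_len(nc) - 0.5) * x$cell_size
  ys <- x$origin[2] - (nr:1 - 0.5) * x$cell_size
  graphics::image(xs, ys, t(v[nr:1, , drop = FALSE]), xlab = "lon",
                  ylab = "lat", main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

## shared-geometry predicate used all over the pipeline
same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_geometry_differs <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry mismatch between %s", what))
  invisible(TRUE)
}

#' Longitude/latitude of cell centres
#'
#' @param r a `grid_raster`.
#' @return list with `lon` (length ncol) and `lat` (length nrow, north first).
#' @export
cell_centers <- function(r) {
  list(lon = r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$cell_size,
       lat = r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * r$cell_size)
}

#' Row/column of the cell containing a point
#'
#' @param r a `grid_raster`.
#' @param lon,lat point coordinates in degrees.
#' @return integer `c(row, col)`, or `NA` if outside the raster.
#' @export
cell_from_lonlat <- function(r, lon, lat) {
  col <- floor((lon - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - lat) / r$cell_size) + 1L
  if (row < 1L || row > nrow(r$values) || col < 1L || col > ncol(r$values))
    return(c(NA_integer_, NA_integer_))
  c(as.integer(row), as.integer(col))
}

#' Read a single-layer raster from file
#'
#' Dispatches on `format` (or the file extension): ESRI ASCII grid
#' (`.asc`/`.agr`) is supported. GeoTIFF and NetCDF are recognised but not
#' handled by this build and raise an informative error.
#'
#' @param path file path.
#' @param format one of `"ascii"`, `"geotiff"`, `"netcdf"`; guessed from the
#'   extension when missing.
#' @return a `grid_raster`.
#' @export
read_raster <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read raster: file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, asc = , agr = , txt = "ascii",
                     tif = , tiff = "geotiff", nc = "netcdf",
                     stop("cannot guess raster format from extension: ", ext))
  }
  switch(match.arg(format, c("ascii", "geotiff", "netcdf")),
         ascii = read_ascii_grid(path),
         stop("format '", format, "' is not supported by this build; ",
              "use ESRI ASCII grids"))
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a `grid_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "xllcenter", "yllcenter", "cellsize", "nodata_value"))
      break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing georeferencing header in ASCII grid: ", path)
  if (is.null(hdr$xllcorner)) {
    if (is.null(hdr$xllcenter))
      stop("missing georeferencing header in ASCII grid: ", path)
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  grid_raster(m, origin, hdr$cellsize, nodata = nodata)
}

#' Write a raster to file
#'
#' @param r a `grid_raster`.
#' @param path destination; ESRI ASCII grid format.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- r$origin[2] - nr * r$cell_size
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", r$origin[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", r$cell_size),
           sprintf("NODATA_value %.10g", r$nodata))
  v[is.na(v)] <- r$nodata
  body <- apply(v, 1L, function(row) paste(formatC(row, format = "g",
                                                   digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Block-mean aggregation to a coarser resolution
#'
#' Each output cell is the mean of the valid cells in the corresponding
#' `factor` x `factor` block; trailing partial blocks (non-divisible
#' dimensions) are averaged over the cells available. Blocks that are
#' entirely missing become `NA`.
#'
#' @param r a `grid_raster`.
#' @param factor integer aggregation factor (>= 1).
#' @return a `grid_raster` with `cell_size * factor`.
#' @export
aggregate_mean <- function(r, factor) {
  stopifnot(inherits(r, "grid_raster"))
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(r)
  v <- r$values
  ri <- ceiling(seq_len(nrow(v)) / factor)  # output row of each input row
  ci <- ceiling(seq_len(ncol(v)) / factor)
  nr <- max(ri); nc <- max(ci)
  grp <- (rep(ci, each = nrow(v)) - 1L) * nr + rep(ri, times = ncol(v))
  sums <- rowsum(ifelse(is.na(as.vector(v)), 0, as.vector(v)), grp)
  cnts <- rowsum(as.numeric(!is.na(as.vector(v))), grp)
  out <- matrix(NA_real_, nr, nc)
  out[as.integer(rownames(sums))] <- ifelse(cnts > 0, sums / cnts, NA_real_)
  grid_raster(out, r$origin, r$cell_size * factor, nodata = r$nodata)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p1,p2 numeric `c(lon, lat)` in degrees, or two-column matrices.
#' @return distance(s) in km.
#' @export
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371)
}

#' Distances (km) from one point to every cell centre
#'
#' @param r a `grid_raster` supplying the geometry.
#' @param lon,lat the reference point, degrees.
#' @return a matrix of distances, same shape as `r$values`.
#' @export
distance_field_km <- function(r, lon, lat) {
  cc <- cell_centers(r)
  pts <- cbind(rep(cc$lon, each = length(cc$lat)),
               rep(cc$lat, times = length(cc$lon)))
  matrix(haversine_km(pts, c(lon, lat)),
         nrow = length(cc$lat), ncol = length(cc$lon))
}

#' Apply a binary mask to a raster
#'
#' @param r a `grid_raster`.
#' @param mask a `grid_raster` with values in \{0, 1\} and the same geometry.
#' @return `r` with cells outside the mask set to `NA`.
#' @export
mask_raster <- function(r, mask) {
  stop_if_geometry_differs(r, mask, "raster and mask")
  v <- r$values
  v[is.na(mask$values) | mask$values == 0] <- NA_real_
  grid_raster(v, r$origin, r$cell_size, nodata = r$nodata)
}

## Bilinear interpolation of a (coarse) raster at arbitrary lon/lat points,
## treating cell centres as nodes and replicating edge values beyond the
## outermost centres. Vectorised over points.
bilinear_at <- function(r, lon, lat) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  ## fractional column/row position in centre coordinates
  fx <- (lon - r$origin[1]) / r$cell_size + 0.5
  fy <- (r$origin[2] - lat) / r$cell_size + 0.5
  fx <- pmin(pmax(fx, 1), nc)
  fy <- pmin(pmax(fy, 1), nr)
  c0 <- pmin(floor(fx), max(nc - 1L, 1L))
  r0 <- pmin(floor(fy), max(nr - 1L, 1L))
  c1 <- pmin(c0 + 1L, nc); r1 <- pmin(r0 + 1L, nr)
  wx <- fx - c0; wy <- fy - r0
  if (nc == 1L) { c0 <- c1 <- rep(1L, length(fx)); wx <- 0 }
  if (nr == 1L) { r0 <- r1 <- rep(1L, length(fy)); wy <- 0 }
  idx <- function(rr, cc) v[cbind(rr, cc)]
  (1 - wy) * ((1 - wx) * idx(r0, c0) + wx * idx(r0, c1)) +
    wy * ((1 - wx) * idx(r1, c0) + wx * idx(r1, c1))
}

## Interpolate coarse raster onto the geometry of `fine` (a grid_raster or a
## list with origin/cell_size and values dims).
bilinear_to_geometry <- function(coarse, fine) {
  cc <- cell_centers(fine)
  lon <- rep(cc$lon, each = length(cc$lat))
  lat <- rep(cc$lat, times = length(cc$lon))
  vals <- bilinear_at(coarse, lon, lat)
  grid_raster(matrix(vals, length(cc$lat), length(cc$lon)),
              fine$origin, fine$cell_size, nodata = fine$nodata)
}
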