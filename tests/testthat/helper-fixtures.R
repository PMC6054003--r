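# Shared tiny fixtures, built in code.

small_cfg <- function(seed = 42L, ...) {
  synthetic_config(grid_shape = c(12L, 12L), n_gcms = 3L, seed = seed,
                   coarse_factor = 4L, ...)
}

# grid_raster from a matrix with unit-test-friendly defaults
gr <- function(m, origin = c(-87, 14), cell = 0.1) {
  grid_raster(as.matrix(m), origin, cell)
}

# weather with fully wet, warm, optimal-plateau days: every stress factor 1
optimal_weather <- function(n_years = 1L, tmax = 30, tmin = 22,
                            rain = 20, srad = 18) {
  structure(list(rain = matrix(rain, 365, n_years),
                 tmax = matrix(tmax, 365, n_years),
                 tmin = matrix(tmin, 365, n_years),
                 srad = matrix(srad, 365, n_years),
                 n_years = n_years, lat = 14),
            class = "daily_weather")
}

flat_climate <- function(nr = 4, nc = 4, prec = 120, tmin = 20, tmax = 30,
                         origin = c(-87, 14), cell = 0.1) {
  monthly_climate(array(prec, c(nr, nc, 12)), array(tmin, c(nr, nc, 12)),
                  array(tmax, c(nr, nc, 12)), origin, cell)
}
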