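#' Calibrate the stochastic daily weather generator
#'
#' Fits generator parameters to a 12-month climatology so that the expected
#' monthly rainfall equals the input monthly totals. Wet-day occurrence
#' follows an order-k Markov chain (k = 1, 2 or 3 previous wet/dry days);
#' the conditional wet probability is a linear blend of the monthly wet-day
#' probability p and the recent wet/dry history,
#' `p_wet(history) = p (1 - r) + r <history>` with geometric history weights
#' (most recent day heaviest) and persistence r, which keeps the stationary
#' wet-day frequency exactly p for any order. Expected wet days per month
#' come from the monthly total P through an empirical link
#' `wet_days = a P^b` (capped at the days in the month). Rain amounts on wet
#' days are gamma with a fixed shape and a month-specific scale chosen so
#' `days x p x shape x scale = P`. Daily temperatures are normal deviates
#' about the monthly means linearly interpolated to days; solar radiation is
#' a clear-sky extraterrestrial envelope times a dry- or wet-day
#' transmissivity.
#'
#' Calibration is deterministic (no random draws).
#'
#' @param prec,tmin,tmax numeric length-12 monthly climatology (mm, degC).
#' @param lat station latitude, degrees (drives the radiation envelope).
#' @param order Markov order k in 1..3 (default 3).
#' @param persistence blend weight r in \[0, 1) on the recent history.
#' @param wetday_a,wetday_b empirical wet-day link coefficients.
#' @param rain_shape gamma shape of wet-day amounts.
#' @param temp_sd SD of daily temperature deviates, degC.
#' @param tau_dry,tau_wet clear-sky transmissivity on dry and wet days.
#' @return an object of class `weather_gen_params`.
#' @export
calibrate_weather <- function(prec, tmin, tmax, lat = 14, order = 3L,
                              persistence = 0.3, wetday_a = 0.7,
                              wetday_b = 0.55, rain_shape = 0.8,
                              temp_sd = 1.2, tau_dry = 0.70, tau_wet = 0.45) {
  stopifnot(length(prec) == 12L, length(tmin) == 12L, length(tmax) == 12L,
            order %in% 1:3, persistence >= 0, persistence < 1,
            rain_shape > 0)
  if (any(!is.finite(prec)) || any(prec < 0))
    stop("monthly precipitation must be finite and >= 0")
  wet_days <- pmin(days_in_month, wetday_a * prec^wetday_b)
  p_wet <- wet_days / days_in_month
  scale <- ifelse(wet_days > 0, (prec / wet_days) / rain_shape, 0)
  ## monthly means anchored at month midpoints, interpolated to 365 days
  mid <- cumsum(days_in_month) - days_in_month / 2
  interp_days <- function(v) {
    x <- c(mid[12] - 365, mid, mid[1] + 365)
    y <- c(v[12], v, v[1])
    stats::approx(x, y, xout = 1:365)$y
  }
  structure(list(p_wet = p_wet, rain_shape = rain_shape, rain_scale = scale,
                 order = as.integer(order), persistence = persistence,
                 tmax_day = interp_days(tmax), tmin_day = interp_days(tmin),
                 temp_sd = temp_sd, lat = lat,
                 tau_dry = tau_dry, tau_wet = tau_wet,
                 monthly_prec = prec),
            class = "weather_gen_params")
}

## daily extraterrestrial radiation, MJ/m2/day (FAO-56)
extraterrestrial_radiation <- function(lat, doy) {
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(dec)))
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' Generate replicate years of daily weather
#'
#' Emits `n_years` independent 365-day years (no leap days) of daily rain,
#' tmax, tmin and solar radiation from calibrated parameters. Replicate
#' years are simulated as parallel chains, each with its own stationary
#' initial wet/dry history, so years are exchangeable. Reproducible given
#' `seed`.
#'
#' @param params a [calibrate_weather()] result.
#' @param n_years number of replicate years (default 99).
#' @param seed integer seed.
#' @return an object of class `daily_weather`: list of 365 x n_years
#'   matrices `rain` (mm), `tmax`, `tmin` (degC), `srad` (MJ/m2/day), plus
#'   `n_years` and `lat`.
#' @export
generate_weather <- function(params, n_years = 99L, seed = 1L) {
  stopifnot(inherits(params, "weather_gen_params"), n_years >= 1L)
  n_years <- as.integer(n_years)
  k <- params$order
  r <- params$persistence
  wts <- 0.5^(seq_len(k) - 1); wts <- wts / sum(wts)  # most recent first
  with_seed(seed, {
    ## pre-draw all random inputs; only the occurrence chain needs a loop
    U <- matrix(stats::runif(365L * n_years), 365L, n_years)
    scaleM <- params$rain_scale[month_of_doy]
    amt <- matrix(stats::rgamma(365L * n_years, shape = params$rain_shape,
                                scale = rep(scaleM, n_years)),
                  365L, n_years)
    dev <- matrix(stats::rnorm(365L * n_years, sd = params$temp_sd),
                  365L, n_years)
    ## initial history at the December wet-day frequency
    hist <- matrix(stats::runif(k * n_years) < params$p_wet[12], k, n_years)
    wet <- matrix(FALSE, 365L, n_years)
    for (d in 1:365) {
      p <- params$p_wet[month_of_doy[d]]
      pcond <- p * (1 - r) + r * as.vector(wts %*% hist)
      w <- U[d, ] < pcond
      wet[d, ] <- w
      if (k > 1L) hist[2:k, ] <- hist[seq_len(k - 1L), , drop = FALSE]
      hist[1L, ] <- w
    }
    rain <- amt * wet
    tn <- params$tmin_day + 0.8 * dev
    tx <- params$tmax_day + dev - 1.0 * wet
    tx <- pmax(tx, tn + 0.1)
    ra <- extraterrestrial_radiation(params$lat, 1:365)
    srad <- ra * (params$tau_dry - (params$tau_dry - params$tau_wet) * wet)
    structure(list(rain = rain, tmax = tx, tmin = tn, srad = srad,
                   n_years = n_years, lat = params$lat),
              class = "daily_weather")
  })
}

#' @export
print.daily_weather <- function(x, ...) {
  cat(sprintf("daily_weather: %d replicate years of 365 days\n", x$n_years))
  cat(sprintf("  annual rain %.0f mm (mean over years); tmax %.1f, tmin %.1f degC\n",
              mean(colSums(x$rain)), mean(x$tmax), mean(x$tmin)))
  invisible(x)
}

#' Write a DSSAT weather (.WTH) file
#'
#' Fixed-width DSSAT format: a header with station metadata (INSI, LAT,
#' LONG, ELEV, TAV, AMP) and one `@DATE SRAD TMAX TMIN RAIN` row per day.
#' TAV is the series mean of (tmax + tmin)/2; AMP is the range of monthly
#' mean temperatures. Years are numbered from `first_year`, 365 days each
#' (DOY 1-365, no leap days).
#'
#' @param series a `daily_weather`.
#' @param station_meta list with `insi` (4-char code), `lat`, `long`,
#'   `elev_m`.
#' @param path output file.
#' @param first_year first calendar year label (default 2001).
#' @return `path`, invisibly.
#' @export
write_wth <- function(series, station_meta, path, first_year = 2001L) {
  stopifnot(inherits(series, "daily_weather"))
  tmean <- (series$tmax + series$tmin) / 2
  tav <- mean(tmean)
  mmeans <- tapply(rowMeans(tmean), month_of_doy, mean)
  amp <- max(mmeans) - min(mmeans)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("*WEATHER DATA : %s (synthetic)", station_meta$insi),
               "",
               "@ INSI      LAT     LONG  ELEV   TAV   AMP REFHT WNDHT",
               sprintf("  %-4s %8.3f %8.3f %5.0f %5.1f %5.1f  2.00  2.00",
                       station_meta$insi, station_meta$lat,
                       station_meta$long, station_meta$elev_m, tav, amp),
               "@DATE  SRAD  TMAX  TMIN  RAIN"), con)
  for (y in seq_len(series$n_years)) {
    yr <- (first_year + y - 1L) %% 100L
    writeLines(sprintf("%02d%03d%6.1f%6.1f%6.1f%6.1f", yr, 1:365,
                       series$srad[, y], series$tmax[, y],
                       series$tmin[, y], series$rain[, y]), con)
  }
  invisible(path)
}

#' Read a DSSAT weather (.WTH) file
#'
#' Parses files written by [write_wth()] (365-day years).
#'
#' @param path file path.
#' @return a `daily_weather` plus a `header` element with TAV/AMP/LAT.
#' @export
read_wth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hline <- grep("^@ INSI", lines) + 1L
  hv <- strsplit(trimws(lines[hline]), "\\s+")[[1]]
  dstart <- grep("^@DATE", lines) + 1L
  rows <- lines[dstart:length(lines)]
  parse_num <- function(a, b) as.numeric(substr(rows, a, b))
  srad <- parse_num(6, 11); tmax <- parse_num(12, 17)
  tmin <- parse_num(18, 23); rain <- parse_num(24, 29)
  ny <- length(rows) %/% 365L
  shape <- function(v) matrix(v, 365L, ny)
  structure(list(rain = shape(rain), tmax = shape(tmax),
                 tmin = shape(tmin), srad = shape(srad),
                 n_years = ny, lat = as.numeric(hv[2]),
                 header = list(insi = hv[1], lat = as.numeric(hv[2]),
                               long = as.numeric(hv[3]),
                               elev_m = as.numeric(hv[4]),
                               tav = as.numeric(hv[5]),
                               amp = as.numeric(hv[6]))),
            class = "daily_weather")
}
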