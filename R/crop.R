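#' Generic soil profiles
#'
#' Single-layer 300-mm bucket parameters for the two generic soils used in
#' the management factorial: volumetric water content at the -1.5 MPa lower
#' limit (`ll`) and at the drained upper limit (`dul`), and a runoff
#' fraction applied to daily rain before infiltration.
#'
#' @param name `"medium_silty_loam"` or `"medium_sandy_loam"`.
#' @return list with `name`, `depth` (mm), `ll`, `dul`, `runoff_curve`.
#' @export
soil_profile <- function(name = c("medium_silty_loam", "medium_sandy_loam")) {
  name <- match.arg(name)
  p <- switch(name,
              medium_silty_loam = list(ll = 0.11, dul = 0.28, runoff = 0.15),
              medium_sandy_loam = list(ll = 0.07, dul = 0.20, runoff = 0.10))
  list(name = name, depth = 300, ll = p$ll, dul = p$dul,
       runoff_curve = p$runoff)
}

#' Cultivar parameters for the yield emulator
#'
#' Cardinal temperatures define a trapezoidal suitability on the daily mean
#' temperature (zero at `t_base` and `t_max`, a plateau of 1 between
#' `t_opt_lo` and `t_opt_hi`), with an additional linear heat penalty of
#' `heat_sens` per degC of daily tmax above `t_max`. Defaults describe
#' Mesoamerican drybean, whose production is limited mainly by maximum
#' temperature.
#'
#' @param name `"ICTA_OSTUA"` (black-seeded cultivar) or `"BAT1289"`
#'   (red-seeded breeding line).
#' @param duration_days,potential_yield,t_base,t_opt_lo,t_opt_hi,t_max,heat_sens
#'   overrides of the per-cultivar defaults.
#' @return list of class `cultivar_params`.
#' @export
cultivar_params <- function(name = c("ICTA_OSTUA", "BAT1289"),
                            duration_days = NULL, potential_yield = NULL,
                            t_base = 8, t_opt_lo = 20, t_opt_hi = 28,
                            t_max = 35, heat_sens = 0.1) {
  name <- match.arg(name)
  def <- switch(name,
                ICTA_OSTUA = list(duration = 75L, potential = 2600),
                BAT1289 = list(duration = 70L, potential = 2800))
  stopifnot(t_base < t_opt_lo, t_opt_lo <= t_opt_hi, t_opt_hi < t_max)
  structure(list(name = name,
                 duration_days = if (is.null(duration_days)) def$duration
                                 else as.integer(duration_days),
                 potential_yield = if (is.null(potential_yield)) def$potential
                                   else potential_yield,
                 t_base = t_base, t_opt_lo = t_opt_lo, t_opt_hi = t_opt_hi,
                 t_max = t_max, heat_sens = heat_sens),
            class = "cultivar_params")
}

#' Fertilizer yield multipliers
#'
#' The emulator has no nutrient process model; fertilizer levels act as
#' yield multipliers. `F1` is 64 kg/ha 12-30-06 at sowing, `F2` is
#' 128 kg/ha 18-46-00, both with a 30 kg N/ha side dressing 22 days after
#' sowing; `none` disables fertilization (default 0.34, i.e. unfertilized
#' yields about a third of the F2 yields).
#'
#' @param none,F1,F2 multipliers in (0, 1].
#' @return named numeric vector.
#' @export
fertilizer_levels <- function(none = 0.34, F1 = 0.7, F2 = 1.0) {
  c(none = none, F1 = F1, F2 = F2)
}

#' The 2 x 2 x 2 management factorial
#'
#' Enumerates the full treatment design: two cultivars (ICTA OSTUA,
#' BAT1289) x two generic soils (medium silty loam, medium sandy loam) x
#' two fertilizer levels (F1, F2) - eight treatments.
#'
#' @param fertilizers character levels to cross (default `c("F1", "F2")`).
#' @return data.frame with columns `cultivar`, `soil`, `fertilizer` and a
#'   compact `id`.
#' @export
treatment_design <- function(fertilizers = c("F1", "F2")) {
  d <- expand.grid(cultivar = c("ICTA_OSTUA", "BAT1289"),
                   soil = c("medium_silty_loam", "medium_sandy_loam"),
                   fertilizer = fertilizers,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$id <- paste(d$cultivar, sub("medium_", "", d$soil), d$fertilizer,
                sep = ".")
  d
}

#' The three Central American planting-season windows
#'
#' Default sowing windows (day-of-year in a 365-day calendar):
#' primera 15 Apr - 30 Jun, postrera 20 Aug - 30 Sep,
#' apante 25 Oct - 5 Dec.
#'
#' @return named list of `c(start, end)` DOY pairs.
#' @export
season_windows <- function() {
  list(primera = c(start = 105L, end = 181L),
       postrera = c(start = 232L, end = 273L),
       apante = c(start = 298L, end = 339L))
}

## Hargreaves-type reference ET (mm/day) from temperature and radiation
reference_et <- function(tmax, tmin, srad) {
  pmax(0.0135 * ((tmax + tmin) / 2 + 17.8) * srad / 2.45, 0)
}

#' One day of the single-layer soil water bucket
#'
#' Adds rain minus simple runoff, caps storage at the drained upper limit
#' (excess drains), then removes actual ET = demand x min(1, ASW/0.5) where
#' ASW is the available-soil-water fraction
#' `(water - ll depth) / ((dul - ll) depth)`.
#'
#' Vectorised over `state`/`rain`/`et_demand`.
#'
#' @param state soil water, mm (within `ll*depth .. dul*depth`).
#' @param rain daily rain, mm (>= 0).
#' @param et_demand daily ET demand, mm.
#' @param soil a [soil_profile()].
#' @return list with `state` (mm), `t_frac` (actual/demand, 1 when demand
#'   is 0), `asw_frac` in \[0, 1\].
#' @export
water_balance_step <- function(state, rain, et_demand, soil) {
  if (any(rain < 0)) stop("negative rain")
  cap_ll <- soil$ll * soil$depth
  cap_dul <- soil$dul * soil$depth
  awc <- cap_dul - cap_ll
  w <- pmin(cap_dul, state + rain * (1 - soil$runoff_curve))
  f <- (w - cap_ll) / awc
  aet <- pmin(et_demand * pmin(1, f / 0.5), w - cap_ll)
  w <- w - aet
  list(state = w,
       t_frac = ifelse(et_demand > 0, aet / et_demand, 1),
       asw_frac = (w - cap_ll) / awc)
}

## circular day-of-year sequence within a 365-day year
wrap_doy <- function(days) ((days - 1L) %% 365L) + 1L

## run the bucket over gathered daily matrices (ndays x ny); returns the
## asw fraction AFTER each day's step and the transpiration fraction
bucket_run <- function(rainM, demandM, soil, state0) {
  nd <- nrow(rainM); ny <- ncol(rainM)
  cap_ll <- soil$ll * soil$depth
  cap_dul <- soil$dul * soil$depth
  awc <- cap_dul - cap_ll
  keep <- 1 - soil$runoff_curve
  state <- rep(state0, length.out = ny)
  asw <- tfrac <- matrix(0, nd, ny)
  ## inlined water_balance_step, day by day (agreement with the public
  ## step function is asserted in the test suite)
  for (d in seq_len(nd)) {
    w <- state + rainM[d, ] * keep
    w[w > cap_dul] <- cap_dul
    avail <- w - cap_ll
    red <- avail / (0.5 * awc)
    red[red > 1] <- 1
    dem <- demandM[d, ]
    aet <- dem * red
    over <- aet > avail
    if (any(over)) aet[over] <- avail[over]
    state <- w - aet
    asw[d, ] <- (state - cap_ll) / awc
    tf <- aet / dem
    tf[dem <= 0] <- 1
    tfrac[d, ] <- tf
  }
  list(asw = asw, t_frac = tfrac, state = state)
}

## crop coefficient by fractional stage of the season
crop_kc <- function(s, duration) {
  frac <- s / duration
  ifelse(frac <= 0.2, 0.4, ifelse(frac <= 0.8, 1.05, 0.7))
}

kc_bare <- 0.3   # bare-soil evaporative demand before sowing

## trapezoidal temperature suitability on daily mean T, with heat penalty
temperature_factor <- function(tmean, tmax, cv) {
  f <- ifelse(tmean <= cv$t_base | tmean >= cv$t_max, 0,
        ifelse(tmean < cv$t_opt_lo,
               (tmean - cv$t_base) / (cv$t_opt_lo - cv$t_base),
        ifelse(tmean <= cv$t_opt_hi, 1,
               (cv$t_max - tmean) / (cv$t_max - cv$t_opt_hi))))
  pen <- pmax(0, 1 - cv$heat_sens * pmax(0, tmax - cv$t_max))
  f * pen
}

#' Find the sowing day within a season window
#'
#' The soil water balance starts at the -1.5 MPa lower limit 60 days before
#' the window opens (wrapping circularly within the same replicate year) and
#' runs forward under bare-soil evaporative demand; the sowing day is the
#' first window day on which the available-soil-water fraction reaches the
#' 50 % trigger.
#'
#' @param weather a `daily_weather` (all replicate years are processed).
#' @param window `c(start, end)` DOY pair (see [season_windows()]).
#' @param soil a [soil_profile()].
#' @param spinup_days water-balance spin-up length before the window.
#' @param trigger ASW fraction that triggers sowing.
#' @return integer vector (length `n_years`) of sowing DOYs, `NA` where the
#'   trigger is never reached.
#' @export
find_sowing_day <- function(weather, window, soil, spinup_days = 60L,
                            trigger = 0.5) {
  days <- wrap_doy(seq.int(window["start"] - spinup_days, window["end"]))
  rainM <- weather$rain[days, , drop = FALSE]
  et0 <- reference_et(weather$tmax[days, , drop = FALSE],
                      weather$tmin[days, , drop = FALSE],
                      weather$srad[days, , drop = FALSE])
  run <- bucket_run(rainM, kc_bare * et0, soil, soil$ll * soil$depth)
  inwin <- seq.int(spinup_days + 1L, length(days))
  hit <- apply(run$asw[inwin, , drop = FALSE] >= trigger, 2L,
               function(v) if (any(v)) which(v)[1] else NA_integer_)
  as.integer(wrap_doy(window["start"] + hit - 1L))
}

## vectorised growth simulation: per-year sowing days, one cultivar/soil,
## fertilizer multiplier applied outside; returns per-year yields (kg/ha)
simulate_years <- function(weather, sow_days, cultivar, soil,
                           fert_mult = 1, spinup_days = 60L) {
  ny <- weather$n_years
  stopifnot(length(sow_days) == ny)
  dur <- cultivar$duration_days
  nd <- spinup_days + dur
  sown <- !is.na(sow_days)
  if (!any(sown)) return(numeric(ny))
  sow0 <- ifelse(sown, sow_days, 1L)
  ## (ndays x ny) DOY index per year, wrapping within the replicate year
  doyM <- wrap_doy(outer(seq_len(nd) - spinup_days - 1L, sow0, `+`))
  iy <- rep(seq_len(ny), each = nd)
  gather <- function(m) matrix(m[cbind(as.vector(doyM), iy)], nd, ny)
  rainM <- gather(weather$rain)
  txM <- gather(weather$tmax); tnM <- gather(weather$tmin)
  et0 <- reference_et(txM, tnM, gather(weather$srad))
  kc <- c(rep(kc_bare, spinup_days), crop_kc(seq_len(dur), dur))
  run <- bucket_run(rainM, kc * et0, soil, soil$ll * soil$depth)
  grow <- seq.int(spinup_days + 1L, nd)
  wfac <- colMeans(run$t_frac[grow, , drop = FALSE])
  tfac <- colMeans(temperature_factor((txM[grow, , drop = FALSE] +
                                       tnM[grow, , drop = FALSE]) / 2,
                                      txM[grow, , drop = FALSE], cultivar))
  yld <- cultivar$potential_yield * fert_mult * wfac * tfac
  yld[!sown] <- 0
  yld
}

#' Simulate one season's yield for one year
#'
#' Yield = potential x fertilizer multiplier x mean daily water-stress
#' factor x mean daily temperature-suitability factor over the growing
#' duration. The water balance is spun up from the lower limit for 60 days
#' before sowing under bare-soil demand, then runs under staged crop
#' coefficients. A missing sowing day yields 0.
#'
#' @param weather a `daily_weather`.
#' @param sow_day sowing DOY (scalar, recycled over years) or per-year
#'   vector; `NA` means no sowing.
#' @param cultivar a [cultivar_params()].
#' @param soil a [soil_profile()].
#' @param fert_mult fertilizer multiplier (see [fertilizer_levels()]).
#' @return numeric vector of per-year yields, kg/ha.
#' @export
simulate_yield <- function(weather, sow_day, cultivar, soil, fert_mult = 1) {
  sow <- rep_len(as.integer(sow_day), weather$n_years)
  simulate_years(weather, sow, cultivar, soil, fert_mult)
}

## weather for one cell of a monthly climate, deterministic per (seed, cell)
cell_weather <- function(scenario, row, col, lat, n_years, seed, ...) {
  m <- climate_at_cell(scenario, row, col)
  params <- calibrate_weather(m$prec, m$tmin, m$tmax, lat = lat, ...)
  nr <- dim(scenario$prec)[1]
  cell_seed <- (as.numeric(seed) * 7919 + (col - 1) * nr + row) %% 2147483647
  generate_weather(params, n_years, seed = cell_seed)
}

## core engine shared by run_grid and run_cells: simulate the treatment set
## at a set of cells for a set of seasons; returns a list
## [[season]] -> matrix (cells x treatments) of mean yields over years
simulate_cells <- function(scenario, cells, seasons, treatments, n_years,
                           seed, gen_args = list()) {
  cc <- cell_centers(grid_raster(matrix(0, dim(scenario$prec)[1],
                                        dim(scenario$prec)[2]),
                                 scenario$origin, scenario$cell_size))
  fert <- fertilizer_levels()
  soils <- unique(treatments$soil)
  combos <- unique(treatments[c("cultivar", "soil")])
  out <- lapply(seasons, function(w)
    matrix(NA_real_, nrow(cells), nrow(treatments),
           dimnames = list(NULL, treatments$id)))
  for (i in seq_len(nrow(cells))) {
    row <- cells$row[i]; col <- cells$col[i]
    wx <- do.call(cell_weather,
                  c(list(scenario, row, col, lat = cc$lat[row],
                         n_years = n_years, seed = seed), gen_args))
    for (s in seq_along(seasons)) {
      sow <- lapply(soils, function(sn)
        find_sowing_day(wx, seasons[[s]], soil_profile(sn)))
      names(sow) <- soils
      ybase <- vector("list", nrow(combos))
      names(ybase) <- paste(combos$cultivar, combos$soil)
      for (j in seq_len(nrow(combos))) {
        cv <- cultivar_params(combos$cultivar[j])
        sl <- soil_profile(combos$soil[j])
        ybase[[paste(combos$cultivar[j], combos$soil[j])]] <-
          simulate_years(wx, sow[[combos$soil[j]]], cv, sl, fert_mult = 1)
      }
      for (t in seq_len(nrow(treatments))) {
        key <- paste(treatments$cultivar[t], treatments$soil[t])
        out[[s]][i, t] <- mean(ybase[[key]] *
                                 fert[[treatments$fertilizer[t]]])
      }
    }
  }
  names(out) <- names(seasons)
  out
}

#' Simulate the treatment factorial over a grid
#'
#' For every valid (masked-in) pixel: calibrate the weather generator from
#' the scenario's monthly climate, generate `n_years` replicate years of
#' daily weather, find the sowing day per soil and replicate year, simulate
#' each treatment's yield, and average over years. Deterministic given
#' `seed`; pixels outside the mask are nodata.
#'
#' @param scenario a `monthly_climate`.
#' @param seasons named list of season windows (see [season_windows()]).
#' @param treatments a [treatment_design()] data.frame.
#' @param n_years replicate years per pixel.
#' @param seed integer seed.
#' @param mask optional binary `grid_raster`; `NULL` runs every pixel.
#' @return nested list: `[[season]][[treatment id]]` -> yield `grid_raster`
#'   (kg/ha, mean over replicate years).
#' @export
run_grid <- function(scenario, seasons = season_windows()["primera"],
                     treatments = treatment_design(), n_years = 20L,
                     seed = 1L, mask = NULL) {
  stopifnot(nrow(treatments) >= 1L)
  d <- dim(scenario$prec)
  if (!is.null(mask)) {
    if (!all(dim(mask$values) == d[1:2]) ||
        any(abs(mask$origin - scenario$origin) > 1e-9))
      stop("geometry mismatch between scenario and mask")
    idx <- which(mask$values == 1)
  } else idx <- seq_len(d[1] * d[2])
  cells <- data.frame(row = ((idx - 1L) %% d[1]) + 1L,
                      col = ((idx - 1L) %/% d[1]) + 1L)
  ymat <- simulate_cells(scenario, cells, seasons, treatments, n_years, seed)
  lapply(ymat, function(m) {
    surfs <- lapply(seq_len(ncol(m)), function(t) {
      v <- matrix(NA_real_, d[1], d[2])
      v[idx] <- m[, t]
      grid_raster(v, scenario$origin, scenario$cell_size)
    })
    names(surfs) <- colnames(m)
    surfs
  })
}

#' Simulate the treatment factorial at selected cells
#'
#' Point-scale counterpart of [run_grid()] used for site-level analyses
#' (per-GCM uncertainty runs, season comparisons, fertilizer-response runs).
#'
#' @param scenario a `monthly_climate`.
#' @param cells data.frame with `row`, `col`.
#' @param seasons named list of season windows.
#' @inheritParams run_grid
#' @return list `[[season]]` -> matrix (cells x treatments) of mean yields.
#' @export
run_cells <- function(scenario, cells, seasons = season_windows()["primera"],
                      treatments = treatment_design(), n_years = 20L,
                      seed = 1L) {
  simulate_cells(scenario, cells, seasons, treatments, n_years, seed)
}
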