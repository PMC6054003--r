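silty <- soil_profile("medium_silty_loam")
sandy <- soil_profile("medium_sandy_loam")

test_that("water balance step: identity, capping, domain errors", {
  mid <- (silty$ll + silty$dul) / 2 * silty$depth
  st <- water_balance_step(mid, 0, 0, silty)
  expect_equal(st$state, mid)
  expect_equal(st$t_frac, 1)
  ## saturating rain caps at the drained upper limit
  st <- water_balance_step(silty$ll * silty$depth, 500, 0, silty)
  expect_equal(st$state, silty$dul * silty$depth)
  expect_equal(st$asw_frac, 1)
  expect_error(water_balance_step(mid, -1, 0, silty), "negative rain")
})

test_that("30-day bucket trajectory equals the step-by-step oracle", {
  rain5 <- c(0, 12, 35, 0, 7)               # printed 5-value series, cycled
  rain <- rep(rain5, 6)
  demand <- rep(4, 30)
  state <- silty$ll * silty$depth
  asw_o <- tf_o <- numeric(30)
  for (d in 1:30) {
    st <- water_balance_step(state, rain[d], demand[d], silty)
    state <- st$state; asw_o[d] <- st$asw_frac; tf_o[d] <- st$t_frac
  }
  run <- bucket_run(matrix(rain, 30), matrix(demand, 30), silty,
                    silty$ll * silty$depth)
  expect_equal(as.vector(run$asw), asw_o)
  expect_equal(as.vector(run$t_frac), tf_o)
  expect_equal(run$state, state)
})

test_that("sowing trigger: never for dry years, first day when wet", {
  win <- season_windows()$primera
  dry <- optimal_weather(2, rain = 0)
  expect_true(all(is.na(find_sowing_day(dry, win, silty))))
  wet <- optimal_weather(2, rain = 25)
  expect_equal(find_sowing_day(wet, win, silty),
               rep(unname(win["start"]), 2L))
})

test_that("a constructed rain series triggers sowing on the predicted day", {
  win <- season_windows()$primera
  wx <- optimal_weather(1, rain = 0)
  ## dry spin-up, then steady rain from the 5th window day onward
  start_rain <- win["start"] + 4L
  wx$rain[start_rain:365, 1] <- 18
  ## oracle: run the public step function forward to find the trigger day
  state <- silty$ll * silty$depth
  days <- (win["start"] - 60L):win["end"]
  et0 <- 0.0135 * ((30 + 22) / 2 + 17.8) * 18 / 2.45
  expected <- NA_integer_
  for (d in days) {
    st <- water_balance_step(state, wx$rain[d, 1], 0.3 * et0, silty)
    state <- st$state
    if (d >= win["start"] && is.na(expected) && st$asw_frac >= 0.5)
      expected <- d
  }
  expect_false(is.na(expected))
  expect_gt(expected, start_rain)  # takes several days to refill from LL
  expect_equal(find_sowing_day(wx, win, silty), expected)
})

test_that("yield reaches potential with full water and plateau temperature", {
  cv <- cultivar_params("ICTA_OSTUA")
  wx <- optimal_weather(1, tmax = 30, tmin = 22, rain = 25)
  y <- simulate_yield(wx, 120L, cv, silty, fert_mult = 1)
  expect_equal(y, cv$potential_yield, tolerance = 1e-6)
  ## fertilizer acts as a pure multiplier
  fert <- fertilizer_levels()
  y_none <- simulate_yield(wx, 120L, cv, silty, fert[["none"]])
  expect_equal(y_none / y, 0.34, tolerance = 1e-9)
  ## no sowing day -> zero yield
  expect_equal(simulate_yield(wx, NA, cv, silty), 0)
})

test_that("yield matches a closed-form product on a constructed year", {
  ## constant sub-optimal temperature, full water: yield =
  ## potential * trapezoid(tmean)
  cv <- cultivar_params("BAT1289")
  wx <- optimal_weather(1, tmax = 24, tmin = 12, rain = 25)  # tmean 18
  y <- simulate_yield(wx, 150L, cv, silty, 1)
  tf <- (18 - cv$t_base) / (cv$t_opt_lo - cv$t_base)
  expect_equal(y, cv$potential_yield * tf, tolerance = 1e-6)
  ## heat penalty beyond t_max on top of the trapezoid
  wx2 <- optimal_weather(1, tmax = 37, tmin = 23, rain = 25)  # tmean 30
  y2 <- simulate_yield(wx2, 150L, cv, silty, 1)
  trap <- (cv$t_max - 30) / (cv$t_max - cv$t_opt_hi)
  pen <- 1 - cv$heat_sens * (37 - cv$t_max)
  expect_equal(y2, cv$potential_yield * trap * pen, tolerance = 1e-6)
})

test_that("emulator invariants: bounds, water monotonicity, heat, fertilizer", {
  p <- calibrate_weather(c(10, 8, 15, 40, 180, 220, 110, 120, 200, 150, 40,
                           15), rep(19, 12), rep(30, 12))
  wx <- generate_weather(p, n_years = 8, seed = 3)
  cv <- cultivar_params("ICTA_OSTUA")
  fert <- fertilizer_levels()
  win <- season_windows()$primera
  sow <- find_sowing_day(wx, win, silty)
  y2 <- simulate_yield(wx, sow, cv, silty, fert[["F2"]])
  expect_true(all(y2 >= 0 & y2 <= cv$potential_yield))
  ## more water never hurts (fixed sowing days)
  wetter <- wx; wetter$rain <- wx$rain + 2
  expect_true(all(simulate_yield(wetter, sow, cv, silty, 1) >=
                    simulate_yield(wx, sow, cv, silty, 1) - 1e-9))
  ## fertilizer ordering none <= F1 <= F2
  y0 <- simulate_yield(wx, sow, cv, silty, fert[["none"]])
  y1 <- simulate_yield(wx, sow, cv, silty, fert[["F1"]])
  expect_true(all(y0 <= y1 & y1 <= y2))
  ## warming above the optimum strictly lowers the temperature factor
  warm <- wx; warm$tmax <- wx$tmax + 4; warm$tmin <- wx$tmin + 4
  expect_true(all(simulate_yield(warm, sow, cv, silty, 1) <
                    simulate_yield(wx, sow, cv, silty, 1)))
})

test_that("the factorial enumerates exactly eight treatments", {
  d <- treatment_design()
  expect_equal(nrow(d), 8L)
  expect_equal(nrow(unique(d[c("cultivar", "soil", "fertilizer")])), 8L)
  expect_setequal(unique(d$cultivar), c("ICTA_OSTUA", "BAT1289"))
  expect_setequal(unique(d$soil),
                  c("medium_silty_loam", "medium_sandy_loam"))
  expect_setequal(unique(d$fertilizer), c("F1", "F2"))
})

test_that("run_grid yields match a nested-loop oracle over pixels and years", {
  cl <- make_baseline_climate(small_cfg())$climate
  ## 2x2 sub-grid: rebuild a small scenario from four cells
  sub <- monthly_climate(cl$prec[1:2, 1:2, , drop = FALSE],
                         cl$tmin[1:2, 1:2, , drop = FALSE],
                         cl$tmax[1:2, 1:2, , drop = FALSE],
                         cl$origin, cl$cell_size)
  tr <- treatment_design()
  out <- run_grid(sub, season_windows()["primera"], tr, n_years = 3,
                  seed = 9)
  expect_length(out$primera, 8L)
  win <- season_windows()$primera
  fert <- fertilizer_levels()
  cc <- cell_centers(grid_raster(matrix(0, 2, 2), sub$origin,
                                 sub$cell_size))
  for (t in c(1L, 6L)) {
    cv <- cultivar_params(tr$cultivar[t])
    sl <- soil_profile(tr$soil[t])
    for (i in 1:2) for (j in 1:2) {
      m <- climate_at_cell(sub, i, j)
      params <- calibrate_weather(m$prec, m$tmin, m$tmax, lat = cc$lat[i])
      seed_ij <- (9 * 7919 + (j - 1) * 2 + i) %% 2147483647
      wx <- generate_weather(params, 3, seed = seed_ij)
      sow <- find_sowing_day(wx, win, sl)
      ys <- vapply(1:3, function(y) {
        one <- structure(list(rain = wx$rain[, y, drop = FALSE],
                              tmax = wx$tmax[, y, drop = FALSE],
                              tmin = wx$tmin[, y, drop = FALSE],
                              srad = wx$srad[, y, drop = FALSE],
                              n_years = 1L, lat = wx$lat),
                         class = "daily_weather")
        simulate_yield(one, sow[y], cv, sl, fert[[tr$fertilizer[t]]])
      }, numeric(1))
      expect_equal(out$primera[[t]]$values[i, j], mean(ys))
    }
  }
  ## n_years = 1 equals the direct single-year call at a pixel
  out1 <- run_grid(sub, season_windows()["primera"], tr[1, ], n_years = 1,
                   seed = 9)
  expect_length(out1$primera, 1L)
  expect_true(all(is.finite(out1$primera[[1]]$values)))
})

test_that("masked pixels come back as nodata", {
  cl <- flat_climate(3, 3, prec = 150, tmin = 20, tmax = 30)
  mask <- gr(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3),
             origin = cl$origin, cell = cl$cell_size)
  out <- run_grid(cl, season_windows()["primera"], treatment_design()[1, ],
                  n_years = 2, seed = 1, mask = mask)
  v <- out$primera[[1]]$values
  expect_equal(sum(is.na(v)), 6L)
  expect_true(all(is.finite(diag(v))))
})
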