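surf <- function(v, nr = 3, nc = 3) gr(matrix(v, nr, nc))

test_that("yield change: identity, arithmetic and loop oracle", {
  b <- list(t1 = surf(1000), t2 = surf(1200))
  expect_equal(yield_change(b, b)$delta$values, matrix(0, 3, 3))
  expect_equal(yield_change(b, b)$relative$values, matrix(0, 3, 3))
  ## baseline 1000, future 620 -> -38 %
  f <- list(t1 = surf(620), t2 = surf(620))
  bb <- list(t1 = surf(1000), t2 = surf(1000))
  expect_equal(yield_change(f, bb)$relative$values, matrix(-38, 3, 3))
  ## 8 random surfaces per scenario vs a per-pixel loop oracle
  set.seed(21)
  mk <- function() lapply(1:8, function(i) surf(runif(9, 500, 2000)))
  fut <- mk(); base <- mk()
  names(fut) <- names(base) <- paste0("t", 1:8)
  ch <- yield_change(fut, base)
  for (i in 1:3) for (j in 1:3) {
    mf <- mean(vapply(fut, function(s) s$values[i, j], numeric(1)))
    mb <- mean(vapply(base, function(s) s$values[i, j], numeric(1)))
    expect_equal(ch$delta$values[i, j], mf - mb)
    expect_equal(ch$relative$values[i, j], 100 * (mf - mb) / mb)
  }
  expect_error(yield_change(fut[1:3], base), "treatment sets differ")
})

test_that("robust RMS scaling: large-sample unit scale and antisymmetry", {
  set.seed(2)
  x <- rnorm(1e5)
  out <- robust_rms_scale(x)
  expect_equal(out$scale, 1, tolerance = 0.02)
  expect_equal(out$z, (x - out$center) / out$scale)
  neg <- robust_rms_scale(-x)
  expect_equal(neg$z, -out$z, tolerance = 1e-10)
  expect_error(robust_rms_scale(rep(5, 10)), "degenerate")
  expect_error(robust_rms_scale(c(1, 2)), "at least 3")
})

test_that("robust RMS scaling excludes a gross outlier, per a hand trace", {
  ## 20 small values + one at 100; the two-pass trace is computed with the
  ## same arithmetic written out longhand
  x <- c(seq(-2, 2, length.out = 20), 100)
  mu1 <- mean(x); s1 <- sqrt(mean((x - mu1)^2))
  keep1 <- abs(x - mu1) <= 3 * s1
  expect_false(keep1[21])                     # excluded after pass 1
  mu2 <- mean(x[keep1]); s2 <- sqrt(mean((x[keep1] - mu2)^2))
  out <- robust_rms_scale(x)
  expect_equal(out$center, mu2)
  expect_equal(out$scale, s2)
  expect_gt(out$z[21], 2)                     # outlier far outside the cutoff
  expect_false(out$included[21])
})

test_that("Gi* matches the brute-force formula on a 5x5 cluster fixture", {
  set.seed(3)
  v <- matrix(rnorm(25, 0, 0.3), 5, 5)
  v[2:3, 2:3] <- v[2:3, 2:3] + 5     # high-value cluster
  r <- gr(v, cell = 0.05)            # ~5.6 km cells
  z <- getis_ord_local(r, d_km = 9)
  ## oracle: direct formula with binary weights incl. self
  cc <- cell_centers(r)
  pts <- cbind(rep(cc$lon, each = 5), rep(cc$lat, times = 5))
  x <- as.vector(v)
  n <- 25; xbar <- mean(x); S <- sqrt(mean(x^2) - xbar^2)
  zo <- numeric(25)
  for (i in 1:25) {
    w <- as.numeric(haversine_km(pts, pts[i, ]) <= 9)
    W <- sum(w)
    zo[i] <- (sum(w * x) - xbar * W) /
      (S * sqrt((n * W - W^2) / (n - 1)))
  }
  expect_equal(as.vector(z$values), zo)
  ## the cluster interior carries the maximum Gi*
  expect_true(which.max(z$values) %in% c(7, 8, 12, 13))
  ## weighted local sums also agree with the direct computation globally
  expect_equal(mean(z$values), mean(zo))
})

test_that("Gi* handles constant fields and tiny inputs", {
  expect_true(all(getis_ord_local(gr(matrix(1, 3, 3)), 50)$values == 0))
  expect_error(getis_ord_local(gr(matrix(c(1, NA, NA, NA), 2, 2)), 10),
               "at least 2")
})

test_that("spot categories follow the z cutoffs and partition the region", {
  z <- surf(c(-2.5, -2, -1.5, -1, -0.5, 0, 0.5, 1, 1.2))
  cl <- classify_spots(z, atlas = NULL)
  v <- as.vector(cl$category$values)
  expect_equal(v, c(1, 1, 2, 2, 0, 0, 0, 3, 3))
  expect_true(all(!is.na(v)))                   # exactly one category each
  ## hotspot/adaptation restricted to the atlas, pressure mapped everywhere
  atlas <- surf(c(1, 0, 0, 1, 1, 1, 1, 1, 0))
  cl2 <- classify_spots(z, atlas)
  v2 <- as.vector(cl2$category$values)
  expect_equal(v2[2], 0)   # z = -2 outside atlas: not a hotspot
  expect_equal(v2[3], 0)   # z = -1.5 outside atlas: not an adaptation spot
  expect_equal(v2[9], 3)   # pressure spot outside the atlas is kept
  expect_equal(unname(spot_counts(cl2)),
               c(sum(v2 == 0), sum(v2 == 1), sum(v2 == 2), sum(v2 == 3)))
})

test_that("classification is invariant to shifting yields by a constant", {
  set.seed(8)
  x <- rnorm(400, -150, 80)
  z1 <- robust_rms_scale(x)$z
  z2 <- robust_rms_scale(x + 500)$z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("standard-normal z fields match the 68/95 tail frequencies", {
  set.seed(13)
  n <- 40000
  z <- gr(matrix(rnorm(n), 200, 200))
  cl <- classify_spots(z, atlas = NULL)
  counts <- spot_counts(cl)
  p_hot <- pnorm(-2); p_adp <- pnorm(-1) - pnorm(-2); p_prs <- 1 - pnorm(1)
  for (pair in list(c(counts[["hotspot"]], p_hot),
                    c(counts[["adaptation"]], p_adp),
                    c(counts[["pressure"]], p_prs))) {
    se <- sqrt(pair[2] * (1 - pair[2]) / n)
    expect_lt(abs(pair[1] / n - pair[2]), 4 * se)
  }
})

test_that("kernel density mask: maxima, blobs and zero threshold", {
  template <- gr(matrix(0, 21, 21), cell = 0.05)
  cc <- cell_centers(template)
  one <- data.frame(lon = cc$lon[11], lat = cc$lat[11])
  kd <- kernel_density_mask(one, template, bandwidth_km = 10,
                            threshold = 0.5)
  expect_equal(which.max(kd$density$values),
               which(outer(1:21, 1:21, function(i, j) i == 11 & j == 11)))
  ## two distant points, small bandwidth: two disjoint blobs
  two <- data.frame(lon = cc$lon[c(3, 19)], lat = cc$lat[c(3, 19)])
  kd2 <- kernel_density_mask(two, template, bandwidth_km = 3,
                             threshold = 0.5)
  m <- kd2$mask$values
  expect_gt(sum(m), 0)
  ## blobs do not touch: no masked cell in the central band
  expect_equal(sum(m[9:13, ]), 0)
  expect_gt(sum(m[1:5, ]), 0); expect_gt(sum(m[17:21, ]), 0)
  ## threshold 0 covers every cell with any density (gaussian: all)
  kd0 <- kernel_density_mask(one, template, bandwidth_km = 3, threshold = 0)
  expect_true(all(kd0$mask$values == 1))
  expect_error(kernel_density_mask(one, template, bandwidth_km = -1),
               "bandwidth")
})

test_that("site-pixel selection equals the brute-force triple filter", {
  cfg <- small_cfg()
  out <- make_baseline_climate(cfg)
  ac <- make_atlas_and_communities(cfg, out$dem)
  cm <- ac$communities[1, ]
  sel <- select_site_pixels(cm, ac$atlas, out$dem)
  nr <- nrow(out$dem$values)
  cc <- cell_centers(out$dem)
  oracle <- integer(0)
  for (col in seq_len(ncol(out$dem$values))) for (row in seq_len(nr)) {
    d <- haversine_km(c(cc$lon[col], cc$lat[row]), c(cm$lon, cm$lat))
    if (d <= 15 && ac$atlas$values[row, col] == 1 &&
        abs(out$dem$values[row, col] - cm$elevation_m) <= 100)
      oracle <- c(oracle, (col - 1L) * nr + row)
  }
  expect_setequal((sel$col - 1L) * nr + sel$row, oracle)
  expect_true(all(sel$dist_km <= 15))
  expect_true(all(abs(sel$elevation_m - cm$elevation_m) <= 100))
})

test_that("elevation filter boundary is inclusive at 100 m, exclusive beyond", {
  atlas <- gr(matrix(1, 5, 5), cell = 0.02)
  dem <- gr(matrix(500, 5, 5), cell = 0.02)
  dem$values[1, 1] <- 601   # 101 m above the community
  dem$values[1, 2] <- 600   # exactly 100 m: kept
  cc <- cell_centers(atlas)
  cm <- list(lon = cc$lon[3], lat = cc$lat[3], elevation_m = 500)
  sel <- select_site_pixels(cm, atlas, dem)
  keys <- paste(sel$row, sel$col)
  expect_false("1 1" %in% keys)
  expect_true("1 2" %in% keys)
  ## flat region, all-in atlas: every pixel within 15 km selected
  dem$values[] <- 500
  sel2 <- select_site_pixels(cm, atlas, dem)
  expect_equal(nrow(sel2), 25L)
  ## empty result warns
  faraway <- list(lon = 0, lat = 0, elevation_m = 500)
  expect_warning(select_site_pixels(faraway, atlas, dem), "no pixels")
})
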