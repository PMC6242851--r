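test_that("bilinear bathymetry lookup is exact at nodes and on affine surfaces", {
  g <- planar_grid(matrix(c(0, 0, 100, 100), 2, 2), 0, 0, 1)
  env <- list(bathymetry = g)
  expect_equal(bathymetry_at(env, 0, 0), 0)
  expect_equal(bathymetry_at(env, 0.5, 0.5), 50)

  # depth = x + 2y reproduced exactly everywhere inside the grid
  xs <- seq(0, 10, by = 0.5); ys <- seq(0, 5, by = 0.5)
  tilt <- planar_grid(outer(ys, xs, function(y, x) x + 2 * y), 0, 0, 0.5)
  env2 <- list(bathymetry = tilt)
  expect_equal(bathymetry_at(env2, 3.25, 1.5), 6.25)
  set.seed(1)
  qx <- runif(50, 0, 10); qy <- runif(50, 0, 5)
  expect_equal(bathymetry_at(env2, qx, qy), qx + 2 * qy, tolerance = 1e-12)

  expect_error(bathymetry_at(env2, 11, 1), "outside")
  # grid cell with depth 50 at a centre: values[iy, ix], so 50 sits at x=1, y=0
  g3 <- planar_grid(matrix(c(10, 20, 50, 40), 2, 2), 0, 0, 1)
  expect_equal(bathymetry_at(list(bathymetry = g3), 1, 0), 50)
})

test_that("ice categories are total, half-open, and dominated by the landfast flag", {
  expect_equal(as.character(ice_category(5, FALSE)), "<=10")
  expect_equal(as.character(ice_category(25, FALSE)), "10-40")
  expect_equal(as.character(ice_category(50, TRUE)), "landfast")
  expect_equal(as.character(ice_category(10, FALSE)), "<=10")
  expect_equal(as.character(ice_category(10 + 1e-9, FALSE)), "10-40")
  expect_equal(as.character(ice_category(c(40, 90, 100), FALSE)),
               c("10-40", "40-90", ">90"))
  set.seed(2)
  cc <- runif(500, 0, 100)
  lf <- runif(500) < 0.3
  out <- ice_category(cc, lf)
  expect_false(any(is.na(out)))
  expect_error(ice_category(-1), "\\[0, 100\\]")
  expect_error(ice_category(101), "\\[0, 100\\]")
})

test_that("datasets round-trip through the on-disk format", {
  ds <- small_pop()
  dir <- tempfile("ds_")
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(ds2$fixes$lat, ds$fixes$lat, tolerance = 1e-9)
  expect_equal(ds2$fixes$time, ds$fixes$time)
  expect_equal(ds2$dives$max_depth, ds$dives$max_depth, tolerance = 1e-9)
  expect_equal(ds2$dives$profile[[3]]$depth, ds$dives$profile[[3]]$depth,
               tolerance = 1e-9)
  expect_equal(ds2$ctd$samples[[1]]$salinity, ds$ctd$samples[[1]]$salinity,
               tolerance = 1e-9)
  expect_equal(ds2$env$bathymetry$values, ds$env$bathymetry$values,
               tolerance = 1e-9)
  expect_equal(length(ds2$env$coastline), length(ds$env$coastline))
  # write -> read -> write is byte-stable (canonical formatting)
  dir2 <- tempfile("ds_")
  write_dataset(ds2, dir2)
  expect_identical(readLines(file.path(dir, "fixes.csv")),
                   readLines(file.path(dir2, "fixes.csv")))
})

test_that("readers handle empty streams and report missing columns", {
  dir <- tempfile("ds_")
  ds <- small_pop()
  write_dataset(ds, dir)
  # empty dive file: header only
  writeLines(paste("dive_id", "seal_id", "start_time", "duration_min",
                   "max_depth", "surface_after_s", "lat", "lon", sep = ","),
             file.path(dir, "dives.csv"))
  writeLines("dive_id,elapsed_fraction,depth", file.path(dir, "dive_profiles.csv"))
  ds2 <- read_dataset(dir)
  expect_equal(nrow(ds2$dives), 0)
  # a single fix survives unchanged
  writeLines(c("seal_id,time,lat,lon,source", "S01,2011-07-20T00:00:00,80.0,12.0,gps"),
             file.path(dir, "fixes.csv"))
  ds3 <- read_dataset(dir)
  expect_equal(nrow(ds3$fixes), 1)
  expect_equal(ds3$fixes$lat, 80.0)
  expect_equal(ds3$fixes$lon, 12.0)
  # missing mandatory column is a format error naming it
  writeLines(c("seal_id,time,lat,source", "S01,2011-07-20T00:00:00,80.0,gps"),
             file.path(dir, "fixes.csv"))
  expect_error(read_dataset(dir), "lon")
})

test_that("validation rejects out-of-range records and duplicate times collapse", {
  ds <- small_pop()
  bad <- ds
  bad$fixes$lat[5] <- 95
  expect_error(validate_dataset(bad), "latitude")
  bad2 <- ds
  bad2$summaries$pct_diving[2] <- bad2$summaries$pct_diving[2] + 10
  expect_error(validate_dataset(bad2), "percentages")
  # duplicated timestamp: first record kept
  fx <- ds$fixes[1:3, ]
  fx$time[2] <- fx$time[1]
  expect_message(out <- pinnitrack:::canonicalise_stream(fx, "time", "fix"),
                 "duplicate")
  expect_equal(nrow(out), 2)
  expect_equal(out$lat[1], fx$lat[1])
})

test_that("generated datasets pass validation cleanly", {
  expect_silent(validate_dataset(small_pop()))
})

test_that("polyline distances match trivial geometry and a circle oracle", {
  seg <- list(data.frame(x = c(-1, 1), y = c(0, 0)))
  expect_equal(distance_to_polylines(0, 1, seg), 1)
  expect_equal(distance_to_polylines(-1, 0, seg), 0)   # on a vertex
  expect_equal(distance_to_polylines(3, 0, seg), 2)    # beyond the endpoint
  # dense circle of radius 5: distance is | |p| - 5 | within one chord step
  th <- seq(0, 2 * pi, length.out = 721)
  circ <- list(data.frame(x = 5 * cos(th), y = 5 * sin(th)))
  step <- 2 * pi * 5 / 720
  set.seed(3)
  px <- runif(200, -8, 8); py <- runif(200, -8, 8)
  d <- distance_to_polylines(px, py, circ)
  expect_lt(max(abs(d - abs(sqrt(px^2 + py^2) - 5))), step)
  expect_error(distance_to_polylines(0, 0, list()), "empty")
})

test_that("polyline distance equals an all-segments brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    lines <- lapply(1:3, function(i)
      data.frame(x = cumsum(rnorm(6)), y = cumsum(rnorm(6))))
    px <- runif(40, -3, 3); py <- runif(40, -3, 3)
    got <- distance_to_polylines(px, py, lines)
    brute <- sapply(seq_along(px), function(q) {
      best <- Inf
      for (ln in lines) for (i in seq_len(nrow(ln) - 1)) {
        a <- c(ln$x[i], ln$y[i]); b <- c(ln$x[i + 1], ln$y[i + 1])
        p <- c(px[q], py[q])
        tt <- max(0, min(1, sum((p - a) * (b - a)) / sum((b - a)^2)))
        best <- min(best, sqrt(sum((p - (a + tt * (b - a)))^2)))
      }
      best
    })
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("planar projection round-trips coordinates near the centre", {
  ctr <- list(lat = 79, lon = 12)
  set.seed(4)
  lat <- 79 + rnorm(100, 0, 0.5); lon <- 12 + rnorm(100, 0, 2)
  p <- project_aeqd(lat, lon, ctr)
  back <- unproject_aeqd(p$x, p$y, ctr)
  expect_equal(back$lat, lat, tolerance = 1e-9)
  expect_equal(back$lon, lon, tolerance = 1e-9)
  # distances from the centre are exact under the azimuthal projection
  d <- great_circle_distance(79, 12, lat, lon)
  expect_equal(sqrt(p$x^2 + p$y^2), d, tolerance = 1e-9)
})
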