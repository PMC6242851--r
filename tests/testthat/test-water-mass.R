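test_that("the six-box scheme partitions the T/S plane", {
  expect_equal(as.character(classify_water_mass(4.0, 35.0)), "AW")
  expect_equal(as.character(classify_water_mass(-1.0, 34.2)), "WCW")
  expect_equal(as.character(classify_water_mass(1.5, 33.5)), "GW")
  expect_equal(as.character(classify_water_mass(0.0, 30)), "LW")
  expect_equal(as.character(classify_water_mass(2.0, 34.3)), "IntW")
  expect_equal(as.character(classify_water_mass(2.0, 34.8)), "TransAW")
  set.seed(1)
  Tv <- runif(2e5, -3, 8); Sv <- runif(2e5, 0, 36)
  cl <- classify_water_mass(Tv, Sv)
  expect_false(any(is.na(cl)))
  # boundary behaviour at +-1e-9 around every threshold
  eps <- 1e-9
  for (S in c(20, 34.3, 35)) {
    expect_equal(as.character(classify_water_mass(-0.5 - eps, S)), "WCW")
    expect_false(as.character(classify_water_mass(-0.5 + eps, S)) == "WCW")
    expect_equal(as.character(classify_water_mass(1 - eps, S)), "LW")
  }
  expect_equal(as.character(classify_water_mass(3 - eps, 34.65)), "TransAW")
  expect_equal(as.character(classify_water_mass(3 + eps, 34.65)), "AW")
  expect_equal(as.character(classify_water_mass(2, 34.65 - eps)), "IntW")
  expect_equal(as.character(classify_water_mass(2, 34.65 + eps)), "TransAW")
  expect_equal(as.character(classify_water_mass(2, 34 - eps)), "GW")
  expect_equal(as.character(classify_water_mass(2, 34 + eps)), "IntW")
  expect_error(classify_water_mass(NA, 34), "finite")
  expect_error(classify_water_mass(2, -1), "negative")
})

make_cast <- function(id, seal, t, x, y, depths, temps, sals) {
  df <- data.frame(cast_id = id, seal_id = seal, time = t, x = x, y = y)
  df$samples <- list(data.frame(depth = depths, temperature = temps,
                                salinity = sals))
  df
}

test_that("single and symmetric casts give exact assignments", {
  t0 <- hours_after(0)
  dive <- data.frame(dive_id = "d1", seal_id = "A", start_time = t0,
                     x = 0, y = 0, max_depth = 40)
  cast <- make_cast("c1", "A", t0, 0, 0, c(1, 20, 60), c(4, 3, 2),
                    c(33, 34, 35))
  a <- assign_ts(dive, cast)
  # linear interpolation at 40 m between (20 m, 3 C) and (60 m, 2 C)
  expect_equal(a$bottom$temperature, 2.5, tolerance = 1e-9)
  expect_equal(a$bottom$salinity, 34.5, tolerance = 1e-9)
  # surface target 1.5 m interpolates the 1 m and 20 m samples
  expect_equal(a$surface$temperature, approx(c(1, 20), c(4, 3), 1.5)$y,
               tolerance = 1e-9)
  # two casts symmetric in time and distance average evenly
  c2 <- rbind(make_cast("c1", "A", t0 - 3600, 5, 0, c(1, 50), c(2, 2), c(33, 33)),
              make_cast("c2", "A", t0 + 3600, -5, 0, c(1, 50), c(4, 4), c(33, 33)))
  a2 <- assign_ts(dive, c2)
  expect_equal(a2$bottom$temperature, 3, tolerance = 1e-9)
  # no eligible cast
  far <- make_cast("c1", "A", t0 + 20 * 86400, 0, 0, c(1, 50), c(2, 2), c(33, 33))
  expect_null(assign_ts(dive, far))
})

test_that("assignments converge to the nearest cast as kernels shrink", {
  t0 <- hours_after(0)
  dive <- data.frame(dive_id = "d1", seal_id = "A", start_time = t0,
                     x = 0, y = 0, max_depth = 30)
  casts <- rbind(make_cast("c1", "A", t0 + 600, 0.5, 0, c(1, 50), c(1, 1), c(33, 33)),
                 make_cast("c2", "A", t0 + 7200, 8, 0, c(1, 50), c(6, 6), c(35, 35)))
  wide <- assign_ts(dive, casts, tau_h = 100, rho_km = 100)
  tight <- assign_ts(dive, casts, tau_h = 0.1, rho_km = 0.5)
  expect_gt(wide$bottom$temperature, 1.5)           # blended
  expect_equal(tight$bottom$temperature, 1, tolerance = 1e-6)  # nearest only
  # invariance to cast order
  rev2 <- assign_ts(dive, casts[2:1, ], tau_h = 100, rho_km = 100)
  expect_equal(rev2$bottom$temperature, wide$bottom$temperature, tolerance = 1e-12)
})

test_that("a two-layer ocean separates surface and bottom classes", {
  # warm fresh glacial water above 50 m, Atlantic Water below
  t0 <- hours_after(0)
  casts <- do.call(rbind, lapply(1:3, function(i)
    make_cast(paste0("c", i), "A", t0 + i * 3600, i, 0,
              c(1, 49, 51, 120), c(3, 3, 3.6, 3.6), c(33, 33, 34.9, 34.9))))
  dives <- data.frame(dive_id = c("d1", "d2"), seal_id = "A",
                      start_time = t0 + c(3600, 7200),
                      x = c(0, 1), y = 0, max_depth = c(100, 110),
                      lat = NA, lon = NA)
  wm <- dive_water_masses(dives, casts, env = list(center = list(lat = 79, lon = 12)))
  expect_true(all(wm$surface_class == "GW"))
  expect_true(all(wm$bottom_class == "AW"))
  expect_equal(same_mass_fraction(wm), 0)
})

test_that("same-mass fractions equal a direct recount", {
  ds <- small_pop()
  wm <- suppressMessages(dive_water_masses(ds$dives, ds$ctd, ds$env))
  f <- same_mass_fraction(wm)
  expect_equal(f, 100 * sum(wm$same_class) / nrow(wm), tolerance = 1e-12)
  per <- same_mass_fraction(wm, by = "seal_id")
  for (i in seq_len(nrow(per))) {
    sub <- wm[wm$seal_id == per$seal_id[i], ]
    expect_equal(per$same_mass_pct[i], 100 * mean(sub$same_class), tolerance = 1e-12)
  }
  # homogeneous synthetic column: always the same class
  hom <- wm[wm$surface_class == wm$bottom_class, ]
  if (nrow(hom)) expect_equal(same_mass_fraction(hom), 100)
})
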