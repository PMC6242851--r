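test_that("the environment generator is deterministic and fjord-shaped", {
  cfg <- sim_config(n_seals = 2, duration_days = 10, seed = 5)
  e1 <- simulate_environment(cfg)
  e2 <- simulate_environment(cfg)
  expect_identical(e1$bathymetry$values, e2$bathymetry$values)
  expect_identical(e1$ice$fields[[1]]$values, e2$ice$fields[[1]]$values)
  # depth ~ 0 at every coastline vertex
  for (ln in e1$coastline)
    expect_true(all(bathymetry_at(e1, ln$x, ln$y) <= 1))
  # monotone non-decreasing depth along offshore transects
  xs <- seq(0, e1$extent_km[1], by = 0.5)
  for (y in c(5, 20, 40))
    expect_true(all(diff(bathymetry_at(e1, xs, rep(y, length(xs)))) >= -1e-9))
  expect_gte(length(e1$glacier_fronts), 1)
  expect_true(all(e1$ice$fields[[1]]$values >= 0 &
                  e1$ice$fields[[1]]$values <= 100))
  expect_error(sim_config(extent_km = c(1, 1)), "extent")
  expect_error(sim_config(fix_rate = 0), "positive")
})

test_that("seal streams honour their behavioural profile", {
  env <- tiny_env()
  cfg <- sim_config(n_seals = 2, duration_days = 10, seed = 5)
  # benthic_fraction = 1: every dive satisfies the benthic rule
  prof <- seal_profile("B1", benthic_fraction = 1)
  s <- simulate_seal(prof, env, cfg, seed = 2)
  p <- project_aeqd(s$dives$lat, s$dives$lon, env$center)
  bathy <- bathymetry_at(env, p$x, p$y)
  expect_true(all(classify_dive(s$dives$max_depth, bathy) == "benthic"))
  # zero haul-out dwell: no haul-out events, none of the time hauled
  prof0 <- seal_profile("H0", state_dwell_means = c(travel = 10, forage = 30,
                                                    haulout = 0))
  s0 <- simulate_seal(prof0, env, cfg, seed = 3)
  expect_equal(nrow(s0$haulouts), 0)
  expect_true(all(s0$truth$state != "haulout"))
  # determinism
  s2 <- simulate_seal(prof, env, cfg, seed = 2)
  expect_identical(s$fixes, s2$fixes)
  s3 <- simulate_seal(prof, env, cfg, seed = 4)
  expect_false(isTRUE(all.equal(s$fixes$lat, s3$fixes$lat)))
  # unreachable preference centre
  bad <- seal_profile("X", preference_center = c(dist_glacier = 500,
                                                 dist_coast = 500, depth = 9000),
                      preference_spread = c(dist_glacier = 0.1,
                                            dist_coast = 0.1, depth = 1))
  expect_error(simulate_seal(bad, env, cfg, seed = 1), "unreachable")
})

test_that("tight preference spreads concentrate foraging in environmental space", {
  env <- tiny_env()
  cfg <- sim_config(n_seals = 2, duration_days = 40, seed = 1)
  prof <- seal_profile("SP", preference_center = c(dist_glacier = 10,
                                                   dist_coast = 5, depth = 60),
                       preference_spread = c(dist_glacier = 0.5,
                                             dist_coast = 0.5, depth = 5))
  s <- simulate_seal(prof, env, cfg, seed = 1)
  # settled foraging positions: drop the first 4 h of each bout (transit to
  # the bout target)
  r <- rle(s$truth$state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- unlist(lapply(which(r$values == "forage"), function(b)
    if (ends[b] - starts[b] >= 4) (starts[b] + 4):ends[b] else integer(0)))
  dg <- distance_to_polylines(s$truth$x[keep], s$truth$y[keep],
                              env$glacier_fronts)
  expect_lt(sd(dg), 2 * 0.5 + 0.6)  # spread plus within-bout movement noise
  expect_equal(mean(dg), 10, tolerance = 0.25)
})

test_that("empirical dwell times track the configured means on long tracks", {
  env <- tiny_env()
  cfg <- sim_config(n_seals = 2, duration_days = 300, seed = 1)
  prof <- seal_profile("DW")
  # pool bouts over three independent seals for statistical power
  lens <- list(); vals <- list()
  for (sd_i in 1:3) {
    s <- simulate_seal(prof, env, cfg, seed = sd_i)
    r <- rle(s$truth$state)
    lens[[sd_i]] <- r$lengths; vals[[sd_i]] <- r$values
  }
  r <- list(lengths = unlist(lens), values = unlist(vals))
  for (st in c("travel", "forage", "haulout")) {
    emp <- mean(r$lengths[r$values == st])
    expect_equal(emp, unname(prof$state_dwell_means[switch(st, travel = "travel",
                                                           forage = "forage",
                                                           haulout = "haulout")]),
                 tolerance = 0.12)
  }
})

test_that("population generation labels specialists and stays reproducible", {
  cfg <- sim_config(n_seals = 2, duration_days = 15, seed = 42)
  ds <- small_pop()
  expect_equal(sort(ds$metadata$label), c("generalist", "specialist"))
  expect_error(simulate_population(sim_config(n_seals = 1)), "at least 2")
  ds2 <- simulate_population(cfg)
  expect_identical(ds$fixes, ds2$fixes)
  expect_identical(ds$metadata$body_mass, ds2$metadata$body_mass)
  ds3 <- simulate_population(sim_config(n_seals = 2, duration_days = 15, seed = 43))
  expect_false(isTRUE(all.equal(ds$fixes$lat, ds3$fixes$lat)))
  expect_silent(validate_dataset(ds))
})
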