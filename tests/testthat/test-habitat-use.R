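test_that("covariate extraction reads the environment correctly", {
  env <- tiny_env()
  gl <- env$glacier_fronts[[1]]
  tr <- data.frame(time = hours_after(c(0, 1, 2)),
                   x = c(gl$x[1], 10, 20), y = c(gl$y[1], 20, 30))
  cv <- extract_covariates(tr, env)
  expect_equal(cv$dist_glacier[1], 0)
  expect_true(all(cv$dist_coast >= 0) && all(cv$bathy_depth >= 0))
  expect_equal(cv$bathy_depth, bathymetry_at(env, tr$x, tr$y))
  # an ice-free environment maps every location to the lowest category
  env0 <- env
  env0$ice <- NULL
  cv0 <- extract_covariates(tr, env0)
  expect_true(all(cv0$ice_category == "<=10"))
  # out-of-grid location is flagged, not fatal
  tr2 <- rbind(tr, data.frame(time = hours_after(3), x = 1e4, y = 1e4))
  expect_message(cv2 <- extract_covariates(tr2, env), "outside")
  expect_false(cv2$valid[4])
})

test_that("a tight-preference seal forages at its target depth", {
  env <- tiny_env()
  cfg <- sim_config(n_seals = 2, duration_days = 30, seed = 9)
  prof <- seal_profile("D30", preference_center = c(dist_glacier = 8,
                                                    dist_coast = 3, depth = 30),
                       preference_spread = c(dist_glacier = 1, dist_coast = 1,
                                             depth = 3))
  s <- simulate_seal(prof, env, cfg, seed = 9)
  tr <- s$truth[s$truth$state == "forage", ]
  cv <- extract_covariates(data.frame(time = tr$time, x = tr$x, y = tr$y), env)
  expect_equal(mean(cv$bathy_depth), 30, tolerance = 10 / 30)
})

test_that("bootstrap intervals behave like percentile bootstrap intervals", {
  # constant data: interval collapses onto the mean
  b <- bootstrap_mean_ci(rep(3.5, 20), reps = 100, seed = 1)
  expect_equal(b$ci_low, 3.5)
  expect_equal(b$ci_high, 3.5)
  # scale equivariance
  set.seed(5)
  z <- rexp(40)
  b1 <- bootstrap_mean_ci(z, reps = 2000, seed = 7)
  b2 <- bootstrap_mean_ci(10 * z, reps = 2000, seed = 7)
  expect_equal(10 * c(b1$mean, b1$ci_low, b1$ci_high),
               c(b2$mean, b2$ci_low, b2$ci_high), tolerance = 1e-9)
  # determinism under seed
  b3 <- bootstrap_mean_ci(z, reps = 2000, seed = 7)
  expect_identical(b1, b3)
  expect_error(bootstrap_mean_ci(1), "at least 2")
})

test_that("bootstrap interval width shrinks like 1/sqrt(n)", {
  set.seed(6)
  ns <- c(50, 100, 200, 400, 800, 1600)
  w <- vapply(seq_along(ns), function(i) {
    z <- rnorm(ns[i])
    b <- bootstrap_mean_ci(z, reps = 2000, seed = 100 + i)
    b$ci_high - b$ci_low
  }, 0)
  slope <- coef(lm(log(w) ~ log(ns)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("seasonal trends recover exact lines and respect invariances", {
  day <- seq(1, 60, by = 1.5)
  # an exact line triggers lm's perfect-fit warning; the slope is still exact
  tr <- suppressWarnings(seasonal_trend(2 * day, day, transform = "identity"))
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_lt(tr$p_value, 1e-10)
  # shift invariance of slope and p-value
  set.seed(8)
  y <- 2 * day + rnorm(length(day))
  t1 <- seasonal_trend(y, day, transform = "identity")
  t2 <- seasonal_trend(y + 100, day, transform = "identity")
  expect_equal(t1$slope, t2$slope, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  # OLS closed form
  expect_equal(t1$slope, cov(day, y) / var(day), tolerance = 1e-12)
  # skewed positive responses are log-transformed under "auto"
  expect_equal(seasonal_trend(exp(y / 20), day)$transform, "log")
  expect_error(seasonal_trend(y[1:5], day[1:5]), ">= 10")
  expect_error(seasonal_trend(y, rep(1, length(y))), "30 days|degenerate")
})

test_that("habitat summaries cover months and pool the whole track", {
  env <- tiny_env()
  set.seed(10)
  tt <- hours_after(seq(0, 70 * 24, by = 6))
  tr <- data.frame(time = tt, x = runif(length(tt), 5, 40),
                   y = runif(length(tt), 5, 50))
  cv <- extract_covariates(tr, env)
  hs <- habitat_summaries(cv, seal_id = "Z", reps = 500, seed = 2)
  expect_true("all" %in% hs$month)
  expect_true(all(hs$ci_low <= hs$mean + 1e-9 & hs$mean <= hs$ci_high + 1e-9))
  expect_setequal(unique(hs$variable),
                  c("dist_coast", "dist_glacier", "bathy_depth"))
})

test_that("the environmental-space kernel UD integrates and finds modes", {
  set.seed(11)
  n <- 400
  one <- data.frame(dist_coast = rnorm(n, 5, 0.8),
                    dist_glacier = rnorm(n, 10, 1),
                    bathy_depth = rnorm(n, 50, 6))
  ud <- env_space_ud(one)
  vol <- prod(vapply(ud$axes, function(a) a[2] - a[1], 0))
  expect_equal(sum(ud$density) * vol, 1, tolerance = 0.02)
  expect_true(all(ud$density >= 0))
  # the modal cell is inside the top-25% mask
  expect_true(ud$mask[which.max(ud$density)])
  expect_equal(mean(ud$mask), 0.25, tolerance = 0.01)
  # two well-separated equal clusters: both modes masked
  two <- one
  two$dist_glacier[1:200] <- rnorm(200, 30, 1)
  ud2 <- env_space_ud(two)
  gx <- ud2$axes$dist_glacier
  near <- function(v) which.min(abs(gx - v))
  slab1 <- ud2$mask[, near(10), ]; slab2 <- ud2$mask[, near(30), ]
  expect_true(any(slab1) && any(slab2))
  # zero-variance axis collapses with a warning
  flat <- one; flat$bathy_depth <- 50
  expect_warning(ud3 <- env_space_ud(flat), "zero variance")
  expect_equal(length(ud3$axes$bathy_depth), 1)
  expect_error(env_space_ud(one[1:10, ]), ">= 50")
})
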