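#' Simulation configuration
#'
#' Defaults define the standing study conditions for the synthetic fjord
#' population: observation rates match the reported daily means for the
#' tagged animals (about 15 GPS fixes, 18 dives and 2 CTD casts per seal per
#' day) and the tracking window starts 19 July, the first transmission day
#' of the study season.
#'
#' @param n_seals number of seals (>= 2; half specialists, half generalists).
#' @param duration_days tracking duration per seal.
#' @param fix_rate,dive_rate,ctd_rate expected observations per day.
#' @param seed master seed; every stream derives from it deterministically.
#' @param extent_km c(x, y) domain size in km.
#' @param cell_km environment grid cell size.
#' @param max_depth_m deepest offshore bathymetry.
#' @param start_date first tracking day (UTC).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_seals = 4, duration_days = 60, fix_rate = 15,
                       dive_rate = 18, ctd_rate = 2, seed = 1,
                       extent_km = c(50, 60), cell_km = 0.5,
                       max_depth_m = 250,
                       start_date = "2011-07-19") {
  if (fix_rate <= 0 || dive_rate <= 0 || ctd_rate <= 0)
    stop("observation rates must be positive")
  if (any(extent_km < 5 * cell_km)) stop("degenerate environment extent")
  structure(list(n_seals = n_seals, duration_days = duration_days,
                 fix_rate = fix_rate, dive_rate = dive_rate, ctd_rate = ctd_rate,
                 seed = seed, extent_km = extent_km, cell_km = cell_km,
                 max_depth_m = max_depth_m,
                 start_date = as_utc(paste0(start_date, " 00:00:00"))),
            class = "sim_config")
}

#' Behavioural profile of a synthetic seal
#'
#' @param id seal id.
#' @param preference_center named vector: target `dist_glacier` (km),
#'   `dist_coast` (km), `depth` (m) of foraging sites.
#' @param preference_spread per-variable sd on the same scale; small spreads
#'   make a habitat specialist, large spreads a generalist.
#' @param state_dwell_means mean bout durations (h) for travelling,
#'   foraging, hauling out. A zero haul-out mean disables hauling out.
#' @param benthic_fraction probability a dive is benthic (to the seafloor).
#' @param step_means mean hourly displacement (km) by state.
#' @param angle_kappa turning-angle concentration by state.
#' @return a list of class `seal_profile`.
#' @export
seal_profile <- function(id,
                         preference_center = c(dist_glacier = 10, dist_coast = 5, depth = 50),
                         preference_spread = c(dist_glacier = 1, dist_coast = 1, depth = 10),
                         state_dwell_means = c(travel = 10, forage = 30, haulout = 5),
                         benthic_fraction = 0.8,
                         step_means = c(travel = 2, forage = 0.4, haulout = 0.001),
                         angle_kappa = c(travel = 4, forage = 0.3, haulout = 0.1)) {
  if (any(preference_spread <= 0)) stop("preference spreads must be positive")
  if (benthic_fraction < 0 || benthic_fraction > 1) stop("benthic_fraction in [0,1]")
  if (any(state_dwell_means < 0) || all(state_dwell_means[1:2] == 0))
    stop("dwell means must be non-negative with active travel/forage states")
  structure(list(id = id, preference_center = preference_center,
                 preference_spread = preference_spread,
                 state_dwell_means = state_dwell_means,
                 benthic_fraction = benthic_fraction,
                 step_means = step_means, angle_kappa = angle_kappa),
            class = "seal_profile")
}

#' Simulate a fjord-like environment
#'
#' Builds an environment stack on a planar km grid: smooth bathymetry that
#' is ~0 at the coast (the x = 0 edge) and deepens monotonically offshore,
#' a coastline polyline, two tidal-glacier-front polylines on the coast, and
#' monthly sea-ice concentration fields with a winter maximum plus a
#' land-fast mask hugging the coast in winter.
#'
#' @param config a [sim_config()].
#' @param seed optional seed override.
#' @return an `environment_stack`.
#' @export
simulate_environment <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed %% 2147483647L)
  ex <- config$extent_km; cell <- config$cell_km
  xs <- seq(0, ex[1], by = cell); ys <- seq(0, ex[2], by = cell)
  # depth: saturating offshore ramp, mildly modulated alongshore;
  # multiplicative form keeps depth 0 at the coast and monotone in x
  depth <- outer(ys, xs, function(y, x)
    config$max_depth_m * (1 - exp(-x / 15)) * (1 + 0.15 * sin(2 * pi * y / 40)))
  bathy <- planar_grid(depth, 0, 0, cell)
  coast <- list(data.frame(x = 0, y = seq(0, ex[2], by = 2)))
  glacier <- list(data.frame(x = 0, y = seq(8, 12, by = 1)),
                  data.frame(x = 0, y = seq(ex[2] - 14, ex[2] - 10, by = 1)))
  # monthly ice fields over the tracking window
  n_months <- max(2L, ceiling(config$duration_days / 30) + 1L)
  dates <- config$start_date + (seq_len(n_months) - 1) * 30 * 86400
  doy <- as.integer(format(dates, "%j"))
  winter <- pmax(0, -cos(2 * pi * (doy - 15) / 365))  # 1 mid-winter, 0 mid-summer
  fields <- lapply(seq_len(n_months), function(i) {
    conc <- outer(ys, xs, function(y, x)
      pmin(100, pmax(0, 95 * winter[i] + 15 * (y / ex[2] - 0.5))))
    planar_grid(conc, 0, 0, cell)
  })
  landfast <- lapply(seq_len(n_months), function(i) {
    m <- outer(ys, xs, function(y, x) winter[i] > 0.6 & x < 3)
    planar_grid(m, 0, 0, cell)
  })
  env <- list(bathymetry = bathy, coastline = coast, glacier_fronts = glacier,
              ice = list(dates = dates, fields = fields, landfast = landfast),
              center = list(lat = 79, lon = 12),
              extent_km = ex)
  class(env) <- "environment_stack"
  env
}

# Per-cell habitat covariates of an environment grid (used to place
# foraging targets in environmental space).
env_cell_table <- function(env) {
  g <- env$bathymetry
  xs <- grid_x(g); ys <- grid_y(g)
  pts <- expand.grid(x = xs, y = ys)
  data.frame(pts,
             depth = as.vector(t(g$values)),
             dist_coast = distance_to_polylines(pts$x, pts$y, env$coastline),
             dist_glacier = distance_to_polylines(pts$x, pts$y, env$glacier_fronts))
}

# Draw one foraging-bout target cell for a seal: cells weighted by a
# Gaussian kernel around the preference centre in environmental space.
draw_bout_target <- function(cells, profile) {
  c0 <- profile$preference_center; s0 <- profile$preference_spread
  z <- ((cells$dist_glacier - c0[["dist_glacier"]]) / s0[["dist_glacier"]])^2 +
       ((cells$dist_coast  - c0[["dist_coast"]])  / s0[["dist_coast"]])^2 +
       ((cells$depth       - c0[["depth"]])       / s0[["depth"]])^2
  if (min(z) > 9 * 3)
    stop("preference centre unreachable in this environment for seal ", profile$id)
  w <- exp(-0.5 * pmin(z, 700))
  i <- sample.int(nrow(cells), 1, prob = w)
  c(x = cells$x[i], y = cells$y[i])
}

# Seasonal two-layer water column: returns list(T, S) at given depths for a
# given day-of-year. Layer properties traverse the six water-mass boxes over
# the year: surface GW -> LW -> WCW, deep IntW -> TransAW -> AW.
seasonal_ts <- function(depths, doy) {
  # piecewise-linear seasonal index: 0 summer (doy 200), 1 autumn, 2 winter
  s <- approx(x = c(0, 200, 290, 350, 366 + 200),
              y = c(2, 0, 1, 2, 0), xout = doy, rule = 2)$y
  surfT <- approx(c(0, 1, 2), c(3.0, 0.2, -1.2), s)$y
  surfS <- approx(c(0, 1, 2), c(32.0, 34.2, 34.5), s)$y
  deepT <- approx(c(0, 1, 2), c(1.6, 2.0, 3.6), s)$y
  deepS <- approx(c(0, 1, 2), c(34.3, 34.9, 34.9), s)$y
  f <- 1 / (1 + exp(-(depths - 40) / 6))  # smooth interface at 40 m
  list(temperature = (1 - f) * surfT + f * deepT,
       salinity = (1 - f) * surfS + f * deepS)
}

#' Simulate one seal's observation streams
#'
#' Runs a 3-state semi-Markov movement process (travelling, foraging,
#' hauling out) on an hourly grid: exponential bout durations, state-specific
#' gamma step lengths and von Mises turning angles, foraging bouts attracted
#' to a bout target drawn near the seal's habitat preference centre, and a
#' frozen position while hauled out. Observation streams (GPS fixes with
#' 36 m error, dives tied to local bathymetry, 6-h activity summaries,
#' haul-out events and two-layer seasonal CTD casts) are sampled from the
#' true track.
#'
#' @param profile a [seal_profile()].
#' @param env an environment from [simulate_environment()].
#' @param config a [sim_config()].
#' @param seed seed for this seal's generator.
#' @return list of streams (`fixes`, `dives`, `summaries`, `haulouts`,
#'   `ctd`) plus `truth` (hourly state/position) and `profile`.
#' @export
simulate_seal <- function(profile, env, config = sim_config(), seed = config$seed) {
  set.seed(seed %% 2147483647L)
  ex <- env$extent_km
  cells <- attr(env, "cell_table")
  if (is.null(cells)) cells <- env_cell_table(env)
  n_h <- config$duration_days * 24L
  t0 <- config$start_date

  dwell <- profile$state_dwell_means
  steps_mean <- profile$step_means; kappa <- profile$angle_kappa
  # state bout sequence (semi-Markov, exponential dwells)
  states <- integer(n_h)
  pos <- matrix(NA_real_, n_h + 1, 2)
  pos[1, ] <- c(runif(1, 5, ex[1] - 5), runif(1, 5, ex[2] - 5))
  heading <- runif(1, -pi, pi)
  trans <- rbind(travel = c(0, .8, .2), forage = c(.7, 0, .3), haulout = c(.4, .6, 0))
  if (dwell[["haulout"]] == 0) trans[, 3] <- 0
  trans <- trans / rowSums(trans)
  h <- 1L; state <- 1L
  target <- draw_bout_target(cells, profile)
  while (h <= n_h) {
    len <- max(1L, round(rexp(1, 1 / max(dwell[state], 1e-9))))
    if (dwell[state] == 0) { state <- sample.int(3, 1, prob = trans[state, ]); next }
    for (k in seq_len(min(len, n_h - h + 1L))) {
      states[h] <- state
      p <- pos[h, ]
      if (state == 3L) {
        pos[h + 1, ] <- p  # hauled out: stationary
      } else if (state == 2L) {
        # foraging: mean-revert to the bout target plus small wander
        pos[h + 1, ] <- p + 0.5 * (target - p) +
          rnorm(2, 0, steps_mean[["forage"]] / sqrt(2))
      } else {
        heading <- heading + rvonmises_centered(1, kappa[["travel"]])
        step <- rgamma(1, shape = 4, rate = 4 / steps_mean[["travel"]])
        pos[h + 1, ] <- p + step * c(cos(heading), sin(heading))
      }
      # reflect into the water-covered domain
      pos[h + 1, 1] <- reflect_into(pos[h + 1, 1], 0.5, ex[1] - 0.5)
      pos[h + 1, 2] <- reflect_into(pos[h + 1, 2], 0.5, ex[2] - 0.5)
      h <- h + 1L
    }
    state <- sample.int(3, 1, prob = trans[state, ])
    if (state == 2L) target <- draw_bout_target(cells, profile)
  }
  times_h <- 0:(n_h)  # hours since t0
  truth <- data.frame(time = t0 + times_h[seq_len(n_h)] * 3600,
                      x = pos[seq_len(n_h), 1], y = pos[seq_len(n_h), 2],
                      state = c("travel", "forage", "haulout")[states])

  interp_pos <- function(th) {  # th in hours since t0, linear on the truth grid
    i <- pmin(pmax(floor(th), 0), n_h - 1)
    a <- th - i
    cbind((1 - a) * pos[i + 1, 1] + a * pos[i + 2, 1],
          (1 - a) * pos[i + 1, 2] + a * pos[i + 2, 2])
  }

  # --- GPS fixes (tag timestamps have whole-second resolution) ---
  nfix <- rpois(1, config$fix_rate * config$duration_days)
  th <- sort(unique(round(runif(nfix, 0, n_h - 1e-3) * 3600))) / 3600
  fp <- interp_pos(th) + matrix(rnorm(2 * length(th), 0, 0.036), ncol = 2)
  ll <- unproject_aeqd(fp[, 1], fp[, 2], env$center)
  fixes <- data.frame(seal_id = profile$id, time = t0 + th * 3600,
                      lat = ll$lat, lon = ll$lon, source = "gps",
                      stringsAsFactors = FALSE)

  # --- dives (only while not hauled out) ---
  ndv <- rpois(1, config$dive_rate * config$duration_days)
  th <- sort(unique(round(runif(ndv, 0, n_h - 1e-3) * 3600))) / 3600
  th <- th[states[floor(th) + 1] != 3L]
  dp <- interp_pos(th)
  bathy <- bathymetry_at(env, dp[, 1], dp[, 2])
  benthic <- runif(length(th)) < profile$benthic_fraction
  md <- ifelse(benthic,
               pmax(1, bathy - runif(length(th), 0, 20)),
               pmax(1, bathy * runif(length(th), 0.1, 0.5)))
  dur <- pmax(0.5, rgamma(length(th), shape = 19, rate = 19 / 6.6))
  surf <- pmax(5, rgamma(length(th), shape = 9, rate = 0.1))
  dll <- unproject_aeqd(dp[, 1], dp[, 2], env$center)
  dives <- data.frame(dive_id = sprintf("%s_d%05d", profile$id, seq_along(th)),
                      seal_id = profile$id, start_time = t0 + th * 3600,
                      duration_min = dur, max_depth = md,
                      surface_after_s = surf, lat = dll$lat, lon = dll$lon,
                      stringsAsFactors = FALSE)
  bf <- pmin(0.9, pmax(0.05, rbeta(length(th), 8, 8)))  # bottom-time fraction
  dives$profile <- lapply(seq_along(th), function(i) {
    b <- bf[i]; d1 <- (1 - b) * 0.55; d2 <- d1 + b
    data.frame(elapsed_fraction = c(0, d1, d2, 1),
               depth = c(0, md[i], md[i], 0))
  })

  # --- haul-out events from the state series ---
  r <- rle(states == 3L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ho <- which(r$values)
  haulouts <- data.frame(seal_id = rep(profile$id, length(ho)),
                         start_time = t0 + (starts[ho] - 1L) * 3600,
                         end_time = t0 + ends[ho] * 3600,
                         stringsAsFactors = FALSE)

  # --- 6-h activity summaries ---
  nper <- config$duration_days * 4L
  per_idx <- rep(seq_len(nper), each = 6L)
  frac_haul <- tapply(states == 3L, per_idx, mean)
  share <- pmin(0.95, pmax(0.6, rnorm(nper, 0.78, 0.03)))
  pct_hauled <- 100 * as.vector(frac_haul)
  pct_diving <- (100 - pct_hauled) * share
  summaries <- data.frame(seal_id = profile$id,
                          period_start = t0 + (seq_len(nper) - 1L) * 6 * 3600,
                          period_hours = 6,
                          pct_diving = pct_diving,
                          pct_surface = 100 - pct_hauled - pct_diving,
                          pct_hauled = pct_hauled,
                          stringsAsFactors = FALSE)

  # --- CTD casts: two-layer seasonal water column ---
  nct <- rpois(1, config$ctd_rate * config$duration_days)
  th <- sort(unique(round(runif(nct, 0, n_h - 1e-3) * 3600))) / 3600
  cp <- interp_pos(th)
  cbat <- bathymetry_at(env, cp[, 1], cp[, 2])
  cll <- unproject_aeqd(cp[, 1], cp[, 2], env$center)
  ctd <- data.frame(cast_id = sprintf("%s_c%04d", profile$id, seq_along(th)),
                    seal_id = profile$id, time = t0 + th * 3600,
                    lat = cll$lat, lon = cll$lon, stringsAsFactors = FALSE)
  doy0 <- as.integer(format(t0, "%j"))
  ctd$samples <- lapply(seq_along(th), function(i) {
    zmax <- max(6, min(cbat[i], 200))
    z <- seq(1.5, zmax, length.out = max(4, ceiling(zmax / 5)))
    ts <- seasonal_ts(z, doy0 + th[i] / 24)
    data.frame(depth = z,
               temperature = ts$temperature + rnorm(length(z), 0, 0.05),
               salinity = pmax(0, ts$salinity + rnorm(length(z), 0, 0.02)))
  })

  list(fixes = fixes, dives = dives, summaries = summaries,
       haulouts = haulouts, ctd = ctd, truth = truth, profile = profile)
}

reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  v <- (v - lo) %% (2 * w)
  lo + ifelse(v > w, 2 * w - v, v)
}

# centred von Mises draws (mean 0) by rejection (Best & Fisher 1979)
rvonmises_centered <- function(n, kappa) {
  if (kappa < 1e-6) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  out
}

#' Simulate a labelled specialist/generalist population
#'
#' Builds an environment and `n_seals` seals: the first half are habitat
#' specialists (tight preference spreads, distinct per-seal glacier-distance
#' targets), the second half generalists (wide spreads). Labels are kept in
#' the metadata for downstream assertions.
#'
#' @param config a [sim_config()].
#' @return a dataset list as in [read_dataset()], plus `env`, per-seal
#'   `truth`, and a `label` column ("specialist"/"generalist") in
#'   `metadata`.
#' @export
simulate_population <- function(config = sim_config()) {
  if (config$n_seals < 2) stop("need at least 2 seals for similarity indices")
  env <- simulate_environment(config, seed = config$seed)
  attr(env, "cell_table") <- env_cell_table(env)
  n_spec <- ceiling(config$n_seals / 2)
  set.seed(config$seed %% 2147483647L)
  lens <- round(rnorm(config$n_seals, 196, 10))
  girths <- round(rnorm(config$n_seals, 171, 8))
  seals <- vector("list", config$n_seals)
  labels <- character(config$n_seals)
  glacier_targets <- seq(4, 20, length.out = max(n_spec, 2))
  for (i in seq_len(config$n_seals)) {
    specialist <- i <= n_spec
    labels[i] <- if (specialist) "specialist" else "generalist"
    id <- sprintf("S%02d", i)
    center <- c(dist_glacier = if (specialist) glacier_targets[i] else 12,
                dist_coast = 4, depth = 60)
    spread <- if (specialist) c(dist_glacier = 0.7, dist_coast = 0.7, depth = 8)
              else c(dist_glacier = 8, dist_coast = 5, depth = 60)
    prof <- seal_profile(id, preference_center = center, preference_spread = spread,
                         benthic_fraction = min(0.95, 0.5 + 0.1 * i))
    seals[[i]] <- simulate_seal(prof, env, config,
                                seed = (config$seed + 7919L * i) %% 2147483647L)
  }
  bind <- function(part) {
    out <- do.call(rbind, lapply(seals, `[[`, part))
    rownames(out) <- NULL
    out
  }
  meta <- seal_metadata(id = sprintf("S%02d", seq_len(config$n_seals)),
                        sex = rep(c("F", "M"), length.out = config$n_seals),
                        standard_length = lens, girth = girths,
                        tag_start = rep(config$start_date, config$n_seals),
                        tag_end = rep(config$start_date +
                                        config$duration_days * 86400, config$n_seals),
                        start_lat = rep(env$center$lat, config$n_seals),
                        start_lon = rep(env$center$lon, config$n_seals))
  meta$label <- labels
  ds <- list(metadata = meta, fixes = bind("fixes"), dives = bind("dives"),
             summaries = bind("summaries"), haulouts = bind("haulouts"),
             ctd = bind("ctd"), env = env,
             truth = setNames(lapply(seals, `[[`, "truth"), meta$id),
             profiles = setNames(lapply(seals, `[[`, "profile"), meta$id))
  validate_dataset(ds)
  ds
}
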