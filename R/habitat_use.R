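#' Habitat covariates along a track
#'
#' For each location: distance to the nearest coastline and tidal glacier
#' front (km), bilinear bathymetric depth (m), and sea-ice concentration
#' with its category from the ice field nearest in date. Locations outside
#' the bathymetry grid are flagged missing and excluded from downstream
#' summaries.
#'
#' @param track data.frame with `time`, `x`, `y` (planar km).
#' @param env an `environment_stack`.
#' @return data.frame: `time`, `x`, `y`, `dist_coast`, `dist_glacier`,
#'   `bathy_depth`, `ice_concentration`, `ice_category`, `valid`.
#' @export
extract_covariates <- function(track, env) {
  n <- nrow(track)
  depth <- rep(NA_real_, n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    depth[i] <- tryCatch(bathymetry_at(env, track$x[i], track$y[i]),
                         error = function(e) NA_real_)
  }
  ok <- !is.na(depth)
  if (any(!ok))
    message(sum(!ok), " location(s) outside the bathymetry grid excluded")
  out <- data.frame(time = track$time, x = track$x, y = track$y,
                    dist_coast = distance_to_polylines(track$x, track$y, env$coastline),
                    dist_glacier = distance_to_polylines(track$x, track$y, env$glacier_fronts),
                    bathy_depth = depth,
                    ice_concentration = NA_real_, valid = ok)
  landfast <- rep(FALSE, n)
  if (!is.null(env$ice)) {
    key <- format(track$time, "%Y-%m-%d")
    for (d in unique(key)) {
      sel <- which(key == d & ok)
      if (!length(sel)) next
      fld <- ice_field_for_date(env, track$time[sel[1]])
      out$ice_concentration[sel] <- grid_bilinear(fld$concentration,
                                                  track$x[sel], track$y[sel])
      lf <- fld$landfast
      lf$values <- lf$values * 1   # logical mask -> numeric for interpolation
      landfast[sel] <- grid_bilinear(lf, track$x[sel], track$y[sel]) > 0.5
    }
    out$ice_concentration <- pmin(100, pmax(0, out$ice_concentration))
  } else {
    out$ice_concentration[ok] <- 0
  }
  out$ice_category <- factor(NA, levels = levels(ice_category(0)))
  out$ice_category[ok] <- ice_category(out$ice_concentration[ok], landfast[ok])
  out
}

#' Bootstrap percentile confidence interval for a mean
#'
#' Nonparametric bootstrap of the sample mean (via `boot::boot`) with a
#' percentile interval, deterministic under the seed.
#'
#' @param values numeric vector, `n >= 2`.
#' @param reps bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return list: `mean`, `ci_low`, `ci_high`, `n`, `reps`.
#' @export
bootstrap_mean_ci <- function(values, reps = 10000, level = 0.95, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values to bootstrap")
  if (sd(values) == 0)
    return(list(mean = mean(values), ci_low = mean(values),
                ci_high = mean(values), n = length(values), reps = reps))
  set.seed(seed %% 2147483647L)
  b <- boot::boot(values, function(d, i) mean(d[i]), R = reps)
  qs <- quantile(b$t[, 1], c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 6)
  list(mean = mean(values), ci_low = qs[1], ci_high = qs[2],
       n = length(values), reps = reps)
}

#' Monthly bootstrap summaries of habitat covariates
#'
#' @param covs an [extract_covariates()] table for one seal.
#' @param variables covariate columns to summarise.
#' @param seal_id id for the output.
#' @inheritParams bootstrap_mean_ci
#' @return data.frame with one row per (month + "all") x variable.
#' @export
habitat_summaries <- function(covs, variables = c("dist_coast", "dist_glacier",
                                                  "bathy_depth"),
                              seal_id = "seal", reps = 10000, seed = 1) {
  covs <- covs[covs$valid, , drop = FALSE]
  mon <- format(covs$time, "%Y-%m")
  groups <- c(list(all = seq_len(nrow(covs))),
              split(seq_len(nrow(covs)), mon))
  out <- NULL
  k <- 0
  for (g in names(groups)) for (v in variables) {
    idx <- groups[[g]]
    if (length(idx) < 2) next
    k <- k + 1
    ci <- bootstrap_mean_ci(covs[[v]][idx], reps = reps, seed = seed + k)
    out <- rbind(out, data.frame(seal_id = seal_id, month = g, variable = v,
                                 mean = ci$mean, ci_low = ci$ci_low,
                                 ci_high = ci$ci_high, n = ci$n,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Seasonal trend test
#'
#' Ordinary least squares of a (possibly log-transformed) response on a
#' running day index (1 = first transmission day), with the two-sided
#' p-value of the slope. By default strictly positive responses with
#' skewness > 1 are log-transformed; otherwise the identity is used.
#'
#' @param values response vector.
#' @param day_index running day number (same length).
#' @param transform "auto", "identity" or "log".
#' @return list: `slope` (per day, on the analysis scale), `p_value`,
#'   `transform`, `intercept`.
#' @export
seasonal_trend <- function(values, day_index, transform = "auto") {
  keep <- is.finite(values) & is.finite(day_index)
  values <- values[keep]; day_index <- day_index[keep]
  if (length(values) < 10 || diff(range(day_index)) < 30)
    stop("need >= 10 observations spanning >= 30 days")
  if (sd(day_index) == 0) stop("degenerate design: day index has no variance")
  skew <- function(z) mean((z - mean(z))^3) / (sd(z)^3 + 1e-300)
  use_log <- switch(transform,
                    log = TRUE, identity = FALSE,
                    auto = all(values > 0) && skew(values) > 1,
                    stop("unknown transform"))
  y <- if (use_log) log(values) else values
  fit <- lm(y ~ day_index)
  s <- summary(fit)$coefficients
  list(slope = s["day_index", "Estimate"],
       p_value = s["day_index", "Pr(>|t|)"],
       transform = if (use_log) "log" else "identity",
       intercept = s["(Intercept)", "Estimate"])
}

#' Environmental-space kernel utilization distribution
#'
#' Product-Gaussian kernel density over (distance to coast, distance to
#' glacier front, depth) evaluated on a 32³ grid spanning the data range
#' padded by one bandwidth per axis, with normal-reference diagonal
#' bandwidths. The "top 25%" mask flags cells whose density is at or above
#' the 75th percentile of all evaluated densities. An axis with zero
#' variance is collapsed (single grid plane) with a warning.
#'
#' @param covs an [extract_covariates()] table (valid rows used), or any
#'   data.frame containing the three variables.
#' @param variables the three axes.
#' @param n_grid grid resolution per axis.
#' @return list of class `env_space_ud`: `axes` (grid coordinates),
#'   `density` (3-d array), `mask` (logical array), `bandwidth`,
#'   `threshold`.
#' @export
env_space_ud <- function(covs, variables = c("dist_coast", "dist_glacier",
                                             "bathy_depth"),
                         n_grid = 32) {
  if (!is.null(covs$valid)) covs <- covs[covs$valid, , drop = FALSE]
  X <- as.matrix(covs[, variables])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 50) stop("need >= 50 complete locations")
  n <- nrow(X)
  bw <- numeric(3); axes <- vector("list", 3)
  for (j in 1:3) {
    sj <- sd(X[, j])
    if (sj == 0) {
      warning("axis ", variables[j], " has zero variance; collapsed")
      bw[j] <- 1
      axes[[j]] <- X[1, j]
    } else {
      # normal-reference rule for d = 3
      bw[j] <- sj * (4 / (5 * n))^(1 / 7)
      axes[[j]] <- seq(min(X[, j]) - bw[j], max(X[, j]) + bw[j],
                       length.out = n_grid)
    }
  }
  K <- lapply(1:3, function(j)
    outer(axes[[j]], X[, j], function(g, x) dnorm(g, x, bw[j])))
  dims <- vapply(axes, length, 1L)
  dens <- array(0, dims)
  for (i in seq_len(n))
    dens <- dens + outer(outer(K[[1]][, i], K[[2]][, i]), K[[3]][, i])
  dens <- dens / n
  thr <- quantile(dens, 0.75, names = FALSE)
  structure(list(axes = setNames(axes, variables), density = dens,
                 mask = dens >= thr, bandwidth = setNames(bw, variables),
                 threshold = thr, n = n),
            class = "env_space_ud")
}
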