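#' Dynamic Brownian bridge motion variance
#'
#' Estimates the Brownian motion variance \eqn{\sigma^2_m} (km²/h) along a
#' track with the sliding-window leave-one-out method: within each window of
#' `window` locations, every odd interior point contributes the likelihood
#' of its position under a Brownian bridge spanning its two neighbours with
#' the given location error. Each window may contain one breakpoint
#' (candidates at least `margin` locations from either end); the
#' constant-variance and best single-break models are compared by BIC.
#' A location covered by several windows takes the mean of its per-window
#' estimates.
#'
#' @param track data.frame with `time`, `x`, `y` (planar km), time-sorted.
#' @param window window size in locations (odd).
#' @param margin margin in locations (odd).
#' @param error_sd_m location error sd, metres.
#' @return numeric vector of \eqn{\sigma^2_m}, one per location.
#' @export
estimate_motion_variance <- function(track, window = 35, margin = 11,
                                     error_sd_m = 50) {
  n <- nrow(track)
  tt <- as.numeric(track$time) / 3600
  err <- error_sd_m / 1000
  # Bridge likelihood pieces for every interior point, precomputed once:
  # deviation from the neighbour-interpolated mean, the bridge-variance
  # coefficient on sigma^2_m, and the error floor. The focal point's own
  # location error is part of the floor, so a stationary jittered track
  # yields sigma^2_m ~ 0.
  ii <- if (n >= 3) 2:(n - 1) else integer(0)
  Tt <- tt[ii + 1] - tt[ii - 1]
  aa <- (tt[ii] - tt[ii - 1]) / Tt
  dev2 <- (track$x[ii] - ((1 - aa) * track$x[ii - 1] + aa * track$x[ii + 1]))^2 +
          (track$y[ii] - ((1 - aa) * track$y[ii - 1] + aa * track$y[ii + 1]))^2
  c1 <- Tt * aa * (1 - aa)
  c2 <- (1 + (1 - aa)^2 + aa^2) * err^2
  # bridge log-likelihood of odd interior points idx (global indices)
  odd_ll <- function(idx, s2m) {
    k <- idx - 1
    v <- c1[k] * s2m + c2[k]
    sum(-log(2 * pi * v) - 0.5 * dev2[k] / v)
  }
  ml_s2 <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    o <- optimize(function(ls) -odd_ll(idx, exp(ls)), c(log(1e-8), log(1e3)))
    exp(o$minimum)
  }
  if (n < window) {
    warning("track shorter than the window; using one global window")
    idx <- seq(2, n - 1, by = 2)
    return(rep(ml_s2(idx), n))
  }
  acc <- numeric(n); cnt <- numeric(n)
  for (s in seq_len(n - window + 1)) {
    e <- s + window - 1
    loc <- seq(s + 1, e - 1, by = 2)        # odd interior points of the window
    bic0 <- -2 * odd_ll(loc, s0 <- ml_s2(loc)) + log(length(loc))
    best <- list(bic = bic0, vals = rep(s0, window))
    for (bp in seq(s + margin, e - margin)) {
      li <- loc[loc < bp]; ri <- loc[loc >= bp]
      if (length(li) < 2 || length(ri) < 2) next
      sl <- ml_s2(li); sr <- ml_s2(ri)
      bic <- -2 * (odd_ll(li, sl) + odd_ll(ri, sr)) + 2 * log(length(loc))
      if (bic < best$bic)
        best <- list(bic = bic,
                     vals = c(rep(sl, bp - s), rep(sr, e - bp + 1)))
    }
    acc[s:e] <- acc[s:e] + best$vals
    cnt[s:e] <- cnt[s:e] + 1
  }
  acc / pmax(cnt, 1)
}

#' Dynamic Brownian bridge utilization distribution
#'
#' Accumulates the time-integrated Gaussian bridge density of every
#' inter-location segment over a regular grid and normalises to a
#' probability surface. The bridge variance at relative position
#' \eqn{\alpha} along a segment of duration \eqn{T} is
#' \eqn{T\alpha(1-\alpha)\sigma^2_m + ((1-\alpha)^2+\alpha^2)\delta^2},
#' with \eqn{\delta} the location error. The grid is the track bounding box
#' padded by 3 times the largest bridge sd; cells are `cell_m` squares.
#'
#' @param track as in [estimate_motion_variance()].
#' @param variances per-location \eqn{\sigma^2_m} (km²/h).
#' @param cell_m grid cell size, metres.
#' @param error_sd_m location error sd, metres.
#' @param nstep bridge discretisation steps per segment.
#' @return object of class `utilization_distribution`: a [planar_grid()] of
#'   cell probabilities plus `cell_km`.
#' @export
compute_ud <- function(track, variances, cell_m = 500, error_sd_m = 50,
                       nstep = 10) {
  n <- nrow(track)
  stopifnot(length(variances) == n)
  tt <- as.numeric(track$time) / 3600
  cell <- cell_m / 1000; err <- error_sd_m / 1000
  dur <- diff(tt)
  s2 <- (variances[-n] + variances[-1]) / 2
  pad <- 3 * sqrt(max(dur * 0.25 * s2 + err^2, err^2))
  xs <- seq(floor((min(track$x) - pad) / cell) * cell,
            max(track$x) + pad, by = cell)
  ys <- seq(floor((min(track$y) - pad) / cell) * cell,
            max(track$y) + pad, by = cell)
  if (n == 1) {
    dx <- outer(rep(1, length(ys)), (xs - track$x)^2)
    dy <- outer((ys - track$y)^2, rep(1, length(xs)))
    m <- exp(-0.5 * (dx + dy) / err^2)
  } else {
    m <- dbbmm_grid_cpp(xs, ys, track$x[-n], track$y[-n], track$x[-1],
                        track$y[-1], dur, s2, err, as.integer(nstep))
  }
  tot <- sum(m)
  if (tot <= 0) stop("empty utilization distribution")
  structure(list(grid = planar_grid(m / tot, xs[1], ys[1], cell),
                 cell_km = cell),
            class = "utilization_distribution")
}

#' Home-range area from a utilization distribution
#'
#' Cumulative-mass contouring: cells are ranked by probability, accumulated
#' until the requested mass is reached, and the area is the cell count times
#' the cell area (so areas are multiples of the cell area).
#'
#' @param ud a [compute_ud()] result.
#' @param level probability level in (0, 1), e.g. 0.5 or 0.95.
#' @return area in km².
#' @export
contour_area <- function(ud, level) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  p <- sort(as.vector(ud$grid$values), decreasing = TRUE)
  ncell <- which(cumsum(p) >= level - 1e-12)[1]
  ncell * ud$cell_km^2
}

#' Monthly and whole-track home ranges
#'
#' Computes 50% and 95% dBBMM home-range areas for the whole track and for
#' each calendar month in which the seal transmitted on at least
#' `min_days` distinct days (months below the threshold are excluded).
#' Motion variances are estimated once on the full track and subset per
#' month.
#'
#' @param track as in [estimate_motion_variance()], one seal.
#' @param seal_id id used in the output.
#' @inheritParams estimate_motion_variance
#' @inheritParams compute_ud
#' @param min_days minimum distinct transmission days per month.
#' @return data.frame: `seal_id`, `period` ("all" or "YYYY-MM"),
#'   `area_50`, `area_95` (km²).
#' @export
monthly_home_ranges <- function(track, seal_id = "seal", window = 35,
                                margin = 11, cell_m = 500, error_sd_m = 50,
                                min_days = 20) {
  v <- estimate_motion_variance(track, window, margin, error_sd_m)
  one <- function(sub, vs, period) {
    ud <- compute_ud(sub, vs, cell_m, error_sd_m)
    data.frame(seal_id = seal_id, period = period,
               area_50 = contour_area(ud, 0.5),
               area_95 = contour_area(ud, 0.95), stringsAsFactors = FALSE)
  }
  out <- one(track, v, "all")
  mon <- format(track$time, "%Y-%m")
  for (m in unique(mon)) {
    sel <- mon == m
    ndays <- length(unique(format(track$time[sel], "%Y-%m-%d")))
    if (ndays < min_days) {
      message("month ", m, " excluded (", ndays, " transmission days)")
      next
    }
    if (sum(sel) < 3) next
    out <- rbind(out, one(track[sel, , drop = FALSE], v[sel], m))
  }
  rownames(out) <- NULL
  out
}
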