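#' Benthic vs pelagic dive classification
#'
#' A dive is benthic when its maximum depth is within `margin_m` of the
#' charted seafloor or exceeds the charted depth (charted bathymetry is
#' imperfect, so over-deep dives count as benthic); both clauses reduce to
#' the single inequality `max_depth >= bathy_depth - margin_m`. Dives with
#' missing bathymetry are `NA` (unclassified).
#'
#' @param max_depth dive maximum depth, m (positive down), vectorised.
#' @param bathy_depth charted depth at the dive location, m.
#' @param margin_m distance-from-bottom margin, m.
#' @return factor "benthic"/"pelagic" (NA where bathymetry is missing).
#' @export
classify_dive <- function(max_depth, bathy_depth, margin_m = 25) {
  if (any(max_depth <= 0, na.rm = TRUE)) stop("dive depth must be positive")
  miss <- is.na(bathy_depth)
  if (any(miss)) message(sum(miss), " dive(s) without bathymetry left unclassified")
  out <- ifelse(max_depth >= bathy_depth - margin_m, "benthic", "pelagic")
  factor(out, levels = c("benthic", "pelagic"))
}

#' Dive-shape phase fractions
#'
#' Splits a dive into descent, bottom and ascent phases: the bottom phase
#' is the elapsed time (linearly interpolated between profile points) spent
#' at or below `bottom_threshold` times the maximum depth; descent is the
#' time before the first bottom entry and ascent the time after the last
#' bottom exit. The three fractions partition the dive.
#'
#' @param profile data.frame with `elapsed_fraction` (in \[0,1\],
#'   increasing) and `depth` (m), at least 4 points, starting and ending at
#'   the surface, reaching the maximum depth.
#' @param bottom_threshold fraction of maximum depth defining the bottom
#'   phase.
#' @return named numeric: `descent`, `bottom`, `ascent` fractions.
#' @export
dive_shape <- function(profile, bottom_threshold = 0.8) {
  f <- profile$elapsed_fraction; z <- profile$depth
  if (length(f) < 4 || any(diff(f) < 0) || f[1] != 0 || f[length(f)] != 1)
    stop("malformed profile: need >= 4 points with elapsed fraction 0..1")
  zmax <- max(z)
  thr <- bottom_threshold * zmax
  # crossing times of the threshold, linearly interpolated
  cross <- numeric(0)
  for (i in seq_len(length(f) - 1)) {
    z0 <- z[i]; z1 <- z[i + 1]
    if ((z0 < thr) != (z1 < thr)) {
      a <- (thr - z0) / (z1 - z0)
      cross <- c(cross, f[i] + a * (f[i + 1] - f[i]))
    }
  }
  at_thr <- f[abs(z - thr) < 1e-12]
  below <- z >= thr
  t_in <- if (length(cross) || length(at_thr)) min(c(cross, at_thr)) else f[which(below)[1]]
  t_out <- if (length(cross) || length(at_thr)) max(c(cross, at_thr)) else f[max(which(below))]
  # integrated time with depth >= threshold
  bottom <- 0
  for (i in seq_len(length(f) - 1)) {
    lo <- f[i]; hi <- f[i + 1]
    z0 <- z[i]; z1 <- z[i + 1]
    if (z0 >= thr && z1 >= thr) bottom <- bottom + (hi - lo)
    else if (z0 >= thr || z1 >= thr) {
      a <- (thr - z0) / (z1 - z0)
      xc <- lo + a * (hi - lo)
      bottom <- bottom + if (z0 >= thr) xc - lo else hi - xc
    }
  }
  descent <- t_in
  ascent <- 1 - t_out
  mid_excursions <- (t_out - t_in) - bottom  # above-threshold time inside the bottom span
  c(descent = descent, bottom = bottom + mid_excursions, ascent = ascent)
}

#' Activity budget from 6-h summaries and haul-out events
#'
#' Time-weighted monthly and overall means of the diving / surface /
#' hauled-out percentages, plus haul-out durations (minutes) and intervals
#' between consecutive haul-outs (hours).
#'
#' @param summaries `SummaryPeriod` stream for one seal.
#' @param haulouts haul-out events for the same seal (may be empty).
#' @return list: `budget` data.frame (month or "all" x three percentages),
#'   `haulout_durations_min`, `interhaulout_hours`.
#' @export
activity_budget <- function(summaries, haulouts = NULL) {
  if (nrow(summaries) == 0) stop("no summary periods")
  if (!is.null(haulouts) && nrow(haulouts) > 1) {
    h <- haulouts[order(haulouts$start_time), ]
    if (any(as.numeric(h$start_time[-1]) < as.numeric(h$end_time[-nrow(h)])))
      stop("overlapping haul-out events")
  }
  mon <- format(summaries$period_start, "%Y-%m")
  w <- summaries$period_hours
  one <- function(sel, label) {
    data.frame(month = label,
               pct_diving = sum(summaries$pct_diving[sel] * w[sel]) / sum(w[sel]),
               pct_surface = sum(summaries$pct_surface[sel] * w[sel]) / sum(w[sel]),
               pct_hauled = sum(summaries$pct_hauled[sel] * w[sel]) / sum(w[sel]),
               n_periods = sum(sel), stringsAsFactors = FALSE)
  }
  budget <- one(rep(TRUE, nrow(summaries)), "all")
  for (m in unique(mon)) budget <- rbind(budget, one(mon == m, m))
  dur <- numeric(0); gaps <- numeric(0)
  if (!is.null(haulouts) && nrow(haulouts)) {
    h <- haulouts[order(haulouts$start_time), ]
    dur <- as.numeric(h$end_time - h$start_time, units = "mins")
    if (nrow(h) > 1)
      gaps <- as.numeric(h$start_time[-1] - h$end_time[-nrow(h)], units = "hours")
  }
  list(budget = budget, haulout_durations_min = dur, interhaulout_hours = gaps)
}

#' PCA of monthly dive variables
#'
#' Standardises a seal-month by variable table and decomposes it by
#' singular values (`prcomp`). Rows with missing cells are dropped and
#' constant variables removed, both with a message/warning. Loadings follow
#' the sign convention that each component's largest-magnitude loading is
#' positive.
#'
#' @param table data.frame/matrix of monthly means; rows are seal-months.
#' @return list of class `pca_result`: `loadings`, `scores`,
#'   `variance_fraction`, `kept_rows`, `kept_vars`.
#' @export
monthly_pca <- function(table) {
  X <- as.matrix(table)
  keep_r <- stats::complete.cases(X)
  if (any(!keep_r)) message(sum(!keep_r), " row(s) with missing cells dropped")
  X <- X[keep_r, , drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("constant variable(s) dropped: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (nrow(X) < 3 || ncol(X) < 2) stop("need >= 3 complete rows and >= 2 variables")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  L <- pc$rotation; S <- pc$x
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]; S[, j] <- -S[, j]
    }
  }
  structure(list(loadings = L, scores = S,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 kept_rows = which(keep_r), kept_vars = colnames(X)),
            class = "pca_result")
}

#' Per-dive metrics table
#'
#' Combines benthic/pelagic classification (against interpolated
#' bathymetry) and dive-shape fractions for a dive stream.
#'
#' @param dives dive stream (with `profile` list-column and planar dive
#'   locations in `x`, `y`, or `lat`/`lon` plus `env$center`).
#' @param env an `environment_stack`.
#' @param margin_m benthic margin, m.
#' @return data.frame keyed by `dive_id` with `bathy_depth`, `dive_class`,
#'   `descent`, `bottom`, `ascent`.
#' @export
dive_metrics <- function(dives, env, margin_m = 25) {
  if (is.null(dives$x)) {
    p <- project_aeqd(dives$lat, dives$lon, env$center)
    dives$x <- p$x; dives$y <- p$y
  }
  bathy <- vapply(seq_len(nrow(dives)), function(i)
    tryCatch(bathymetry_at(env, dives$x[i], dives$y[i]),
             error = function(e) NA_real_), 0)
  cls <- classify_dive(dives$max_depth, bathy, margin_m)
  sh <- t(vapply(dives$profile, dive_shape, numeric(3)))
  data.frame(dive_id = dives$dive_id, seal_id = dives$seal_id,
             start_time = dives$start_time, max_depth = dives$max_depth,
             duration_min = dives$duration_min,
             surface_after_s = dives$surface_after_s,
             bathy_depth = bathy, dive_class = cls,
             descent = sh[, "descent"], bottom = sh[, "bottom"],
             ascent = sh[, "ascent"], stringsAsFactors = FALSE)
}
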