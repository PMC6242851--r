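#' Water-mass classification scheme
#'
#' The six temperature/salinity classes of west-Svalbard fjord and shelf
#' water, evaluated in order (first match wins), which partitions the
#' (T, S) plane:
#' \itemize{
#'   \item WCW  Winter-Cooled Water: T < -0.5, any S
#'   \item LW   Local Water: -0.5 <= T < 1, any S
#'   \item GW   modified Glacial Water: T >= 1, S < 34
#'   \item IntW Intermediate Water: T >= 1, 34 <= S < 34.65
#'   \item TransAW Transformed Atlantic Water: 1 <= T < 3, S >= 34.65
#'   \item AW   Atlantic Water: T >= 3, S >= 34.65
#' }
#'
#' @return character vector of class names in evaluation order.
#' @export
water_mass_classes <- function() c("WCW", "LW", "GW", "IntW", "TransAW", "AW")

#' @rdname water_mass_classes
#' @param temperature deg C, vectorised.
#' @param salinity PSU, >= 0, vectorised.
#' @return `classify_water_mass`: factor with the six class levels.
#' @export
classify_water_mass <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(!is.finite(salinity)))
    stop("temperature and salinity must be finite")
  if (any(salinity < 0)) stop("negative salinity")
  out <- ifelse(temperature < -0.5, "WCW",
         ifelse(temperature < 1, "LW",
         ifelse(salinity < 34, "GW",
         ifelse(salinity < 34.65, "IntW",
         ifelse(temperature < 3, "TransAW", "AW")))))
  factor(out, levels = water_mass_classes())
}

# Linear depth interpolation of one CTD cast at a target depth; returns
# c(T, S, dz) where dz is the unspanned depth gap (0 when covered), or NULL
# when the target exceeds the deepest sample by more than zeta_m.
interp_cast <- function(samples, z, zeta_m) {
  zs <- samples$depth
  if (z <= zs[1]) return(c(samples$temperature[1], samples$salinity[1], zs[1] - z))
  if (z > zs[length(zs)]) {
    gap <- z - zs[length(zs)]
    if (gap > zeta_m) return(NULL)
    return(c(samples$temperature[length(zs)], samples$salinity[length(zs)], gap))
  }
  Tv <- approx(zs, samples$temperature, z)$y
  Sv <- approx(zs, samples$salinity, z)$y
  c(Tv, Sv, 0)
}

#' Assign temperature and salinity to a dive
#'
#' A three-way weighted average over nearby CTD casts: each cast within the
#' time window is interpolated in depth to the target (surface 1.5 m and
#' maximum dive depth) and weighted by Gaussian kernels in time gap, planar
#' distance and depth gap, `exp(-dt^2/2tau^2) exp(-dx^2/2rho^2)
#' exp(-dz^2/2zeta^2)`; the `K` highest-weight casts contribute. Classes
#' come from [classify_water_mass()].
#'
#' @param dive one row of a dive stream with planar `x`, `y`, `start_time`,
#'   `max_depth`.
#' @param profiles CTD stream (with planar `x`, `y` and `samples`),
#'   normally the same seal's casts.
#' @param tau_h,rho_km,zeta_m,K kernel scales (hours, km, m) and the number
#'   of casts used.
#' @param window_days candidate casts must be within this many days.
#' @return list: `surface` and `bottom` (each `temperature`, `salinity`,
#'   `class`), `same_class`, `total_weight`; or `NULL` when no cast is
#'   eligible.
#' @export
assign_ts <- function(dive, profiles, tau_h = 48, rho_km = 25, zeta_m = 10,
                      K = 10, window_days = 10) {
  if (nrow(profiles) == 0) return(NULL)
  dt_h <- abs(as.numeric(profiles$time) - as.numeric(dive$start_time)) / 3600
  cand <- which(dt_h <= window_days * 24)
  if (!length(cand)) return(NULL)
  dx <- sqrt((profiles$x[cand] - dive$x)^2 + (profiles$y[cand] - dive$y)^2)
  one_target <- function(z) {
    vals <- lapply(cand, function(i) interp_cast(profiles$samples[[i]], z, zeta_m))
    keep <- !vapply(vals, is.null, TRUE)
    if (!any(keep)) return(NULL)
    V <- do.call(rbind, vals[keep])
    w <- exp(-dt_h[cand][keep]^2 / (2 * tau_h^2)) *
         exp(-dx[keep]^2 / (2 * rho_km^2)) *
         exp(-V[, 3]^2 / (2 * zeta_m^2))
    ord <- order(w, decreasing = TRUE)[seq_len(min(K, sum(keep)))]
    w <- w[ord]; V <- V[ord, , drop = FALSE]
    Tv <- sum(w * V[, 1]) / sum(w)
    Sv <- sum(w * V[, 2]) / sum(w)
    list(temperature = Tv, salinity = Sv,
         class = classify_water_mass(Tv, Sv), weight = sum(w))
  }
  surf <- one_target(1.5)
  bot <- one_target(dive$max_depth)
  if (is.null(surf) || is.null(bot)) return(NULL)
  list(surface = surf, bottom = bot,
       same_class = as.character(surf$class) == as.character(bot$class),
       total_weight = surf$weight + bot$weight)
}

#' Water-mass assignment for a dive stream
#'
#' Applies [assign_ts()] to every dive of a seal (casts restricted to the
#' same seal unless `pool_seals`). Dives with no eligible cast are dropped
#' with a message.
#'
#' @param dives dive stream with planar coordinates (`x`, `y` added if
#'   absent, via `env$center`).
#' @param ctd CTD stream with `samples`.
#' @param env environment (projection centre).
#' @param pool_seals use all seals' casts for every dive.
#' @inheritParams assign_ts
#' @return data.frame: per assigned dive, surface/bottom T, S and class,
#'   `same_class`.
#' @export
dive_water_masses <- function(dives, ctd, env, tau_h = 48, rho_km = 25,
                              zeta_m = 10, K = 10, window_days = 10,
                              pool_seals = FALSE) {
  if (is.null(dives$x)) {
    p <- project_aeqd(dives$lat, dives$lon, env$center)
    dives$x <- p$x; dives$y <- p$y
  }
  if (is.null(ctd$x)) {
    p <- project_aeqd(ctd$lat, ctd$lon, env$center)
    ctd$x <- p$x; ctd$y <- p$y
  }
  rows <- vector("list", nrow(dives))
  for (i in seq_len(nrow(dives))) {
    prof <- if (pool_seals) ctd else ctd[ctd$seal_id == dives$seal_id[i], ]
    a <- assign_ts(dives[i, ], prof, tau_h, rho_km, zeta_m, K, window_days)
    if (is.null(a)) next
    rows[[i]] <- data.frame(dive_id = dives$dive_id[i], seal_id = dives$seal_id[i],
                            start_time = dives$start_time[i],
                            surface_temp = a$surface$temperature,
                            surface_sal = a$surface$salinity,
                            surface_class = as.character(a$surface$class),
                            bottom_temp = a$bottom$temperature,
                            bottom_sal = a$bottom$salinity,
                            bottom_class = as.character(a$bottom$class),
                            same_class = a$same_class,
                            stringsAsFactors = FALSE)
  }
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped) message(skipped, " dive(s) had no eligible CTD cast")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no dive could be assigned a water mass")
  rownames(out) <- NULL
  out
}

#' Percentage of dives with the same water mass at surface and depth
#'
#' @param assignments a [dive_water_masses()] table.
#' @param by optional grouping column(s), e.g. `seal_id`.
#' @return percentage (0-100), or a data.frame per group.
#' @export
same_mass_fraction <- function(assignments, by = NULL) {
  if (is.null(by)) return(100 * mean(assignments$same_class))
  agg <- aggregate(assignments$same_class,
                   by = assignments[, by, drop = FALSE],
                   FUN = function(z) 100 * mean(z))
  names(agg)[ncol(agg)] <- "same_mass_pct"
  agg
}
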