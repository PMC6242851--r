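#' Continuous-time correlated random walk track model
#'
#' Fits the integrated Ornstein-Uhlenbeck velocity model to GPS fixes by
#' maximising the exact Kalman-filter likelihood, with a stopping model for
#' haul-outs: during reported haul-out intervals the velocity state is
#' pinned to zero and the position does not diffuse. The two free
#' parameters are the velocity autocorrelation \eqn{\beta} (1/h) and the
#' velocity scale \eqn{\sigma} (km/h^{1/2}); GPS measurement error is fixed
#' (36 m by default). Optimisation is on \eqn{(\log\beta, \log\sigma)} with
#' random restarts under a fixed seed.
#'
#' @param fixes data.frame with `time` (POSIXct) and planar `x`, `y` (km)
#'   for one seal, time-sorted.
#' @param haulouts data.frame with `start_time`, `end_time` (may be empty).
#' @param error_sd_m GPS error sd in metres.
#' @param n_restarts random restarts.
#' @param seed seed for the restarts.
#' @return object of class `ctcrw_fit` with elements `beta`, `sigma`,
#'   `error_sd_m`, `loglik`, `converged`.
#' @export
fit_ctcrw <- function(fixes, haulouts = NULL, error_sd_m = 36,
                      n_restarts = 5, seed = 1) {
  if (nrow(fixes) < 10) stop("need at least 10 fixes")
  tt <- as.numeric(fixes$time) / 3600  # hours
  if (diff(range(tt)) < 24) stop("fixes must span more than 24 h")
  if (sd(fixes$x) + sd(fixes$y) < 1e-9 && is.null(haulouts))
    message("all fixes effectively coincident; sigma will shrink to zero")
  grid <- ctcrw_grid(fixes, haulouts, times = NULL)
  err_km <- error_sd_m / 1000
  negll <- function(p) {
    v <- -ctcrw_loglik_cpp(grid$t, grid$x, grid$y, grid$hauled,
                           exp(p[1]), exp(p[2]), err_km)
    if (!is.finite(v)) 1e10 else v
  }
  # moment-based centre for the restarts
  dt <- pmax(diff(tt), 1e-3)
  sp <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2) / dt
  sig0 <- max(median(sp), 1e-3)
  set.seed(seed %% 2147483647L)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    p0 <- c(log(1) + rnorm(1, 0, 1), log(sig0) + rnorm(1, 0, 1))
    fit <- tryCatch(
      optim(p0, negll, method = "L-BFGS-B",
            lower = c(log(1e-4), log(1e-6)), upper = c(log(1e3), log(1e3)),
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("CTCRW fit failed in every restart")
  structure(list(beta = exp(best$par[1]), sigma = exp(best$par[2]),
                 error_sd_m = error_sd_m, loglik = -best$value,
                 converged = best$convergence == 0),
            class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat("CTCRW fit: beta =", signif(x$beta, 4), "1/h, sigma =",
      signif(x$sigma, 4), "km/h^1/2, logLik =", round(x$loglik, 2),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# Build the filtering grid: observation times plus optional prediction
# times and haul-out boundaries; per-interval hauled flags.
ctcrw_grid <- function(fixes, haulouts, times) {
  tt <- as.numeric(fixes$time) / 3600
  extra <- as.numeric(times) / 3600
  hb <- if (!is.null(haulouts) && nrow(haulouts))
    c(as.numeric(haulouts$start_time), as.numeric(haulouts$end_time)) / 3600
  else numeric(0)
  allt <- sort(unique(round(c(tt, extra, hb), 9)))
  ix <- match(round(tt, 9), allt)
  x <- rep(NA_real_, length(allt)); y <- rep(NA_real_, length(allt))
  x[ix] <- fixes$x; y[ix] <- fixes$y
  hauled <- integer(length(allt) - 1)
  if (length(hb)) {
    mid <- (allt[-1] + allt[-length(allt)]) / 2
    for (i in seq_len(nrow(haulouts))) {
      s <- as.numeric(haulouts$start_time[i]) / 3600
      e <- as.numeric(haulouts$end_time[i]) / 3600
      hauled[mid > s & mid < e] <- 1L
    }
  }
  list(t = allt, x = x, y = y, hauled = hauled,
       obs_index = ix)
}

#' Predict positions from a CTCRW fit
#'
#' Runs the Kalman filter and Rauch-Tung-Striebel smoother over the union
#' of observation and requested times and returns the posterior mean
#' position and its standard deviation at each requested time. Within
#' haul-out intervals the position is constant (the interval's entry
#' position) and the `hauled` flag is set.
#'
#' @param fit a [fit_ctcrw()] result.
#' @param fixes,haulouts as in [fit_ctcrw()].
#' @param times POSIXct vector of requested times, within
#'   `[first fix - 6 h, last fix + 6 h]`.
#' @return data.frame of class `interpolated_track`: `time`, `x`, `y`,
#'   `sd` (km), `hauled`.
#' @export
predict_positions <- function(fit, fixes, haulouts = NULL, times) {
  tr <- range(as.numeric(fixes$time))
  bad <- as.numeric(times) < tr[1] - 6 * 3600 | as.numeric(times) > tr[2] + 6 * 3600
  if (any(bad))
    stop("requested times outside the fitted window: ",
         paste(utils::head(format(times[bad]), 3), collapse = ", "))
  grid <- ctcrw_grid(fixes, haulouts, times)
  sm <- ctcrw_smooth(grid, fit$beta, fit$sigma, fit$error_sd_m / 1000)
  ix <- match(round(as.numeric(times) / 3600, 9), round(grid$t, 9))
  hauled <- rep(FALSE, length(times))
  if (!is.null(haulouts) && nrow(haulouts)) {
    for (i in seq_len(nrow(haulouts)))
      hauled <- hauled | (times >= haulouts$start_time[i] &
                          times <= haulouts$end_time[i])
  }
  out <- data.frame(time = times, x = sm$mx[ix], y = sm$my[ix],
                    sd = sqrt(pmax(sm$p00[ix], 0)), hauled = hauled)
  class(out) <- c("interpolated_track", "data.frame")
  out
}

# R-level Kalman filter + RTS smoother (2x2 per coordinate; x and y share
# the covariance recursion). Returns smoothed position means and variance.
ctcrw_smooth <- function(grid, beta, sigma, err_km) {
  tt <- grid$t; n <- length(tt)
  R <- err_km^2; s2 <- sigma^2
  mxf <- matrix(0, n, 2); myf <- matrix(0, n, 2)  # filtered means
  Pf <- matrix(0, n, 3)                            # filtered cov (p00,p01,p11)
  mxp <- matrix(0, n, 2); myp <- matrix(0, n, 2)  # predicted
  Pp <- matrix(0, n, 3)
  Tm <- vector("list", n)
  first <- which(!is.na(grid$x))[1]
  for (i in seq_len(n)) {
    if (i < first) next
    if (i == first) {
      mxp[i, ] <- c(grid$x[i], 0); myp[i, ] <- c(grid$y[i], 0)
      Pp[i, ] <- c(R, 0, s2 / (2 * beta))
      Tm[[i]] <- diag(2)
    } else {
      dt <- tt[i] - tt[i - 1]
      if (grid$hauled[i - 1] == 1) {
        Tr <- matrix(c(1, 0, 0, 0), 2, 2)
        q <- c(0, 0, 0)
      } else {
        eb <- exp(-beta * dt)
        Tr <- matrix(c(1, 0, (1 - eb) / beta, eb), 2, 2)
        q <- c(s2 / beta^2 * (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta)),
               s2 * (1 - 2 * eb + eb^2) / (2 * beta^2),
               s2 * (1 - eb^2) / (2 * beta))
      }
      Tm[[i]] <- Tr
      mxp[i, ] <- as.vector(Tr %*% mxf[i - 1, ])
      myp[i, ] <- as.vector(Tr %*% myf[i - 1, ])
      P <- matrix(c(Pf[i - 1, 1], Pf[i - 1, 2], Pf[i - 1, 2], Pf[i - 1, 3]), 2, 2)
      PP <- Tr %*% P %*% t(Tr) + matrix(c(q[1], q[2], q[2], q[3]), 2, 2)
      Pp[i, ] <- c(PP[1, 1], PP[1, 2], PP[2, 2])
    }
    if (!is.na(grid$x[i])) {
      S <- Pp[i, 1] + R
      k0 <- Pp[i, 1] / S; k1 <- Pp[i, 2] / S
      mxf[i, ] <- mxp[i, ] + c(k0, k1) * (grid$x[i] - mxp[i, 1])
      myf[i, ] <- myp[i, ] + c(k0, k1) * (grid$y[i] - myp[i, 1])
      Pf[i, ] <- c((1 - k0) * Pp[i, 1], (1 - k0) * Pp[i, 2],
                   Pp[i, 3] - k1 * Pp[i, 2])
    } else {
      mxf[i, ] <- mxp[i, ]; myf[i, ] <- myp[i, ]
      Pf[i, ] <- Pp[i, ]
    }
  }
  # RTS backward pass
  mxs <- mxf; mys <- myf; Ps <- Pf
  for (i in (n - 1):1) {
    if (i < first) { mxs[i, ] <- mxs[first, ]; mys[i, ] <- mys[first, ]
                     Ps[i, ] <- Ps[first, ]; next }
    Tr <- Tm[[i + 1]]
    P <- matrix(c(Pf[i, 1], Pf[i, 2], Pf[i, 2], Pf[i, 3]), 2, 2)
    PPn <- matrix(c(Pp[i + 1, 1], Pp[i + 1, 2], Pp[i + 1, 2], Pp[i + 1, 3]), 2, 2)
    Ci <- tryCatch(solve(PPn + diag(1e-12, 2)), error = function(e) NULL)
    if (is.null(Ci)) next
    G <- P %*% t(Tr) %*% Ci
    mxs[i, ] <- mxf[i, ] + as.vector(G %*% (mxs[i + 1, ] - mxp[i + 1, ]))
    mys[i, ] <- myf[i, ] + as.vector(G %*% (mys[i + 1, ] - myp[i + 1, ]))
    PSn <- matrix(c(Ps[i + 1, 1], Ps[i + 1, 2], Ps[i + 1, 2], Ps[i + 1, 3]), 2, 2)
    PS <- P + G %*% (PSn - PPn) %*% t(G)
    Ps[i, ] <- c(PS[1, 1], PS[1, 2], PS[2, 2])
  }
  # rows before the first observation carry no filtered state; report the
  # smoothed values there for both
  if (first > 1) Pf[seq_len(first - 1), ] <- Ps[seq_len(first - 1), ]
  list(mx = mxs[, 1], my = mys[, 1], p00 = Ps[, 1], filt_p00 = Pf[, 1])
}

#' Simulate a CTCRW track (for model checking)
#'
#' Draws exact discrete-time realisations of the integrated OU model at the
#' given times, plus GPS noise, to support simulation-based parameter
#' recovery.
#'
#' @param times POSIXct times.
#' @param beta,sigma model parameters.
#' @param error_sd_m GPS error sd (m).
#' @param x0,v0 initial position (km) / velocity (km/h) (2-vectors).
#' @param seed seed.
#' @return data.frame `time`, `x`, `y` (observed with error) plus
#'   `true_x`, `true_y`.
#' @export
simulate_ctcrw <- function(times, beta = 1, sigma = 2, error_sd_m = 36,
                           x0 = c(0, 0), v0 = c(0, 0), seed = 1) {
  set.seed(seed %% 2147483647L)
  tt <- as.numeric(times) / 3600
  n <- length(tt)
  pos <- matrix(0, n, 2); vel <- matrix(0, n, 2)
  pos[1, ] <- x0; vel[1, ] <- v0
  s2 <- sigma^2
  for (i in 2:n) {
    dt <- tt[i] - tt[i - 1]
    eb <- exp(-beta * dt)
    q11 <- s2 / beta^2 * (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta))
    q12 <- s2 * (1 - 2 * eb + eb^2) / (2 * beta^2)
    q22 <- s2 * (1 - eb^2) / (2 * beta)
    Q <- matrix(c(q11, q12, q12, q22), 2, 2)
    L <- chol(Q + diag(1e-14, 2))
    for (c in 1:2) {
      e <- as.vector(t(L) %*% rnorm(2))
      pos[i, c] <- pos[i - 1, c] + vel[i - 1, c] * (1 - eb) / beta + e[1]
      vel[i, c] <- vel[i - 1, c] * eb + e[2]
    }
  }
  err <- error_sd_m / 1000
  data.frame(time = times,
             x = pos[, 1] + rnorm(n, 0, err), y = pos[, 2] + rnorm(n, 0, err),
             true_x = pos[, 1], true_y = pos[, 2])
}
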