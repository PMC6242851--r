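dvonmises_log <- function(x, mu, kappa) {
  kappa * cos(x - mu) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
}

# Unpack the working parameter vector of an n-state HMM with covariate-
# dependent multinomial-logit transitions (diagonal reference, 0).
hmm_unpack <- function(par, n_states, n_cov) {
  k <- n_states
  list(shape = exp(pmin(par[1:k], 20)),
       rate = exp(pmin(par[k + 1:k], 20)),
       kappa = exp(pmin(par[2 * k + 1:k], 10)),
       mu = atan2(sin(par[3 * k + 1:k]), cos(par[3 * k + 1:k])),
       tbeta = matrix(par[4 * k + seq_len(k * (k - 1) * (1 + n_cov))],
                      nrow = 1 + n_cov))  # columns: off-diagonal (i,j) pairs
}

# Per-time transition array (T x k x k) from logit coefficients and a
# covariate design matrix Z (T x (1+ncov), first column 1).
hmm_trans_array <- function(tbeta, Z, n_states) {
  Tn <- nrow(Z); k <- n_states
  eta <- Z %*% tbeta                    # T x k(k-1)
  tr <- array(0, c(Tn, k, k))
  col <- 0
  for (i in seq_len(k)) {
    ex <- matrix(1, Tn, k)              # reference: eta_ii = 0
    for (j in seq_len(k)) {
      if (i == j) next
      col <- col + 1
      ex[, j] <- exp(pmin(eta[, col], 50))
    }
    tr[, i, ] <- ex / rowSums(ex)
  }
  tr
}

hmm_logdens <- function(steps, angles, p) {
  Tn <- length(steps); k <- length(p$shape)
  ld <- matrix(0, Tn, k)
  ok_a <- !is.na(angles)
  for (j in seq_len(k)) {
    ld[, j] <- dgamma(pmax(steps, 1e-9), shape = p$shape[j], rate = p$rate[j],
                      log = TRUE)
    ld[ok_a, j] <- ld[ok_a, j] + dvonmises_log(angles[ok_a], p$mu[j], p$kappa[j])
  }
  ld
}

#' Fit a hidden Markov model to movement steps and angles
#'
#' Three behavioural states with gamma step-length and von Mises
#' turning-angle emissions, and transition probabilities that depend on
#' covariates (proportion of time diving and hauled out, standardised)
#' through a multinomial logit. The forward-algorithm likelihood is
#' maximised numerically from `n_restarts` seeded random initialisations.
#'
#' @param steps step lengths (km) per interval, > 0.
#' @param angles turning angles (radians), `NA` allowed (e.g. first step).
#' @param covariates matrix/data.frame of transition covariates
#'   (standardised internally), or `NULL`.
#' @param n_states number of states.
#' @param n_restarts random initialisations.
#' @param seed RNG seed.
#' @return object of class `hmm_model`: parameter list, `loglik`,
#'   `n_states`, covariate scaling, `converged`.
#' @export
fit_hmm <- function(steps, angles = NULL, covariates = NULL, n_states = 3,
                    n_restarts = 3, seed = 1) {
  Tn <- length(steps)
  if (all(steps <= 0)) stop("degenerate emissions: all steps are zero")
  if (is.null(angles)) angles <- rep(NA_real_, Tn)
  Z <- matrix(1, Tn, 1)
  cov_center <- NULL; cov_scale <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    cov_center <- colMeans(C)
    cov_scale <- apply(C, 2, sd)
    cov_scale[cov_scale == 0] <- 1
    Z <- cbind(1, sweep(sweep(C, 2, cov_center), 2, cov_scale, "/"))
  }
  n_cov <- ncol(Z) - 1
  k <- n_states
  delta <- rep(1 / k, k)
  negll <- function(par) {
    p <- hmm_unpack(par, k, n_cov)
    v <- -hmm_forward_cpp(hmm_logdens(steps, angles, p),
                          as.vector(hmm_trans_array(p$tbeta, Z, k)), delta)
    if (!is.finite(v)) 1e10 else v
  }
  # quantile-split moment initialisation for the step distribution
  qs <- quantile(steps[steps > 0], probs = seq(0, 1, length.out = k + 1))
  grp <- cut(steps, unique(qs), include.lowest = TRUE, labels = FALSE)
  set.seed(seed %% 2147483647L)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    m <- vapply(seq_len(k), function(j) {
      s <- steps[which(grp == j)]
      if (length(s) < 2) c(mean(steps), sd(steps) + 1e-3)
      else c(mean(s), max(sd(s), 1e-3))
    }, numeric(2))
    mu0 <- m[1, ] * exp(rnorm(k, 0, 0.3)); sd0 <- m[2, ] * exp(rnorm(k, 0, 0.3))
    shape0 <- (mu0 / sd0)^2; rate0 <- mu0 / sd0^2
    tb0 <- matrix(rnorm(k * (k - 1) * (1 + n_cov), 0, 0.2), nrow = 1 + n_cov)
    tb0[1, ] <- rnorm(k * (k - 1), -2, 0.3)
    par0 <- c(log(shape0), log(rate0), log(runif(k, 0.3, 2)), rnorm(k, 0, 0.5),
              as.vector(tb0))
    fit <- tryCatch(optim(par0, negll, method = "BFGS",
                          control = list(maxit = 300, reltol = 1e-9)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("HMM fit failed in every restart")
  p <- hmm_unpack(best$par, k, n_cov)
  structure(list(par = best$par, params = p, n_states = k, n_cov = n_cov,
                 cov_center = cov_center, cov_scale = cov_scale,
                 delta = delta, loglik = -best$value,
                 converged = best$convergence == 0),
            class = "hmm_model")
}

hmm_design <- function(model, covariates, Tn) {
  if (is.null(covariates)) return(matrix(1, Tn, 1))
  C <- as.matrix(covariates)
  cbind(1, sweep(sweep(C, 2, model$cov_center), 2, model$cov_scale, "/"))
}

#' @rdname fit_hmm
#' @param model a fitted `hmm_model`.
#' @return `viterbi_states`: integer vector of decoded states (1-based).
#' @export
viterbi_states <- function(model, steps, angles = NULL, covariates = NULL) {
  Tn <- length(steps)
  if (is.null(angles)) angles <- rep(NA_real_, Tn)
  Z <- hmm_design(model, covariates, Tn)
  as.integer(hmm_viterbi_cpp(
    hmm_logdens(steps, angles, model$params),
    as.vector(hmm_trans_array(model$params$tbeta, Z, model$n_states)),
    model$delta))
}

#' @rdname fit_hmm
#' @return `hmm_loglik`: forward log-likelihood at the fitted parameters
#'   for the supplied data.
#' @export
hmm_loglik <- function(model, steps, angles = NULL, covariates = NULL) {
  Tn <- length(steps)
  if (is.null(angles)) angles <- rep(NA_real_, Tn)
  Z <- hmm_design(model, covariates, Tn)
  hmm_forward_cpp(hmm_logdens(steps, angles, model$params),
                  as.vector(hmm_trans_array(model$params$tbeta, Z,
                                            model$n_states)),
                  model$delta)
}

#' Map decoded states to behavioural labels
#'
#' The haul-out state is the one with the highest mean hauled-out covariate
#' among its decoded intervals; of the remaining two, foraging is the state
#' with the shorter mean step length and travelling the other. Ties break
#' by state index.
#'
#' @param decoded integer state sequence.
#' @param steps step lengths aligned with `decoded`.
#' @param hauled_prop haul-out proportion covariate aligned with `decoded`.
#' @return character vector with names `1:3` mapping state index to
#'   "travelling"/"foraging"/"haulout".
#' @export
label_states <- function(decoded, steps, hauled_prop) {
  k <- max(3, max(decoded))
  mean_haul <- vapply(seq_len(k), function(s)
    if (any(decoded == s)) mean(hauled_prop[decoded == s]) else -Inf, 0)
  if (all(mean_haul <= 0))
    warning("hauled-out covariate never positive; haul-out label is nominal")
  haul <- which.max(mean_haul)
  rest <- setdiff(seq_len(k), haul)
  mean_step <- vapply(rest, function(s)
    if (any(decoded == s)) mean(steps[decoded == s]) else Inf, 0)
  forage <- rest[which.min(mean_step)]
  travel <- setdiff(rest, forage)[1]
  out <- character(k)
  out[haul] <- "haulout"; out[forage] <- "foraging"; out[travel] <- "travelling"
  setNames(out, as.character(seq_len(k)))
}

#' k-nearest-neighbour mean distances
#'
#' Mean Euclidean distance from each point to its `k` nearest neighbours
#' (self excluded); the sorted values are the input to the changepoint rule
#' that picks the DBSCAN epsilon.
#'
#' @param xy matrix/data.frame with 2 columns.
#' @param k number of neighbours.
#' @return numeric vector, one per point.
#' @export
knn_mean_dist <- function(xy, k) {
  D <- as.matrix(dist(xy))
  diag(D) <- Inf
  apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
}

#' Single mean changepoint (at most one change, Gaussian cost)
#'
#' Minimises the Gaussian likelihood cost of splitting a series into two
#' constant-mean segments; the split is kept if it beats the no-change cost
#' by the penalty `2 log(n)` (two extra parameters).
#'
#' @param v numeric series.
#' @param min_seg minimum segment length.
#' @return index of the first point of the second segment, or `NA` if no
#'   significant change.
#' @export
mean_changepoint <- function(v, min_seg = 2) {
  n <- length(v)
  if (n < 2 * min_seg) return(NA_integer_)
  cost <- function(z) {
    s2 <- mean((z - mean(z))^2)
    length(z) * log(max(s2, 1e-12))
  }
  null_cost <- cost(v)
  best <- Inf; arg <- NA_integer_
  for (tau in seq(min_seg + 1, n - min_seg + 1)) {
    cc <- cost(v[seq_len(tau - 1)]) + cost(v[tau:n])
    if (cc < best) { best <- cc; arg <- tau }
  }
  if (best + 2 * log(n) < null_cost) arg else NA_integer_
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distances: a core point has at least
#' `min_pts` points (itself included) within `eps`; clusters are the
#' density-connected components of core points plus their border points.
#'
#' @param xy matrix/data.frame with 2 columns.
#' @param eps neighbourhood radius.
#' @param min_pts minimum neighbourhood size for a core point.
#' @return integer cluster labels (0 = noise).
#' @export
dbscan_cluster <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  D <- as.matrix(dist(xy))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Select the foraging area of a 3-day interval
#'
#' Implements the density-clustering rule: epsilon is the sorted
#' k-nearest-neighbour mean distance at its single mean changepoint
#' (median if no significant change), DBSCAN is run with `min_pts`, and the
#' member of the largest cluster closest to that cluster's centroid is the
#' interval's foraging area.
#'
#' @param xy foraging locations (planar km), matrix or data.frame.
#' @param min_pts DBSCAN minimum points (k-nearest-neighbour k is
#'   `min_pts - 1`).
#' @return list `(index, x, y, eps, cluster_size)` or `NULL` if there are
#'   fewer than `min_pts` locations or all points are noise.
#' @export
select_foraging_area <- function(xy, min_pts = 5) {
  xy <- as.matrix(as.data.frame(xy)[, 1:2])
  n <- nrow(xy)
  if (n < min_pts) return(NULL)
  v <- sort(knn_mean_dist(xy, min_pts - 1))
  cp <- mean_changepoint(v)
  eps <- if (is.na(cp)) {
    message("no kNN-distance changepoint; eps set to the median")
    median(v)
  } else v[cp]
  labels <- dbscan_cluster(xy, eps, min_pts)
  if (all(labels == 0L)) {
    message("all points classified as noise; no foraging area")
    return(NULL)
  }
  sizes <- table(labels[labels > 0])
  big <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(labels == big)
  cen <- colMeans(xy[members, , drop = FALSE])
  d <- sqrt((xy[members, 1] - cen[1])^2 + (xy[members, 2] - cen[2])^2)
  idx <- members[which.min(d)]
  list(index = idx, x = xy[idx, 1], y = xy[idx, 2], eps = eps,
       cluster_size = length(members))
}

#' Pairwise environmental similarity indices
#'
#' For each unordered pair of a seal's foraging areas, the absolute
#' difference in an environmental variable is compared with the reference
#' distribution of cross differences between that seal's areas and all
#' other seals' areas: the index is the proportion of reference differences
#' strictly smaller than the pair's difference. 0 marks a habitat
#' specialist (within-seal differences smaller than almost all
#' between-seal differences) and 1 a generalist.
#'
#' @param areas data.frame with `seal_id` and the variable column; one row
#'   per foraging area.
#' @param variable column name to compare.
#' @param reference "cross" (focal-vs-other differences, default) or
#'   "within_others" (adds pairs among other seals' areas).
#' @return list per seal: data.frame `pairs` (i, j, diff, index) and
#'   `mean_index`; plus a `summary` data.frame.
#' @export
similarity_indices <- function(areas, variable, reference = c("cross", "within_others")) {
  reference <- match.arg(reference)
  ids <- unique(areas$seal_id)
  if (length(ids) < 2) stop("need at least 2 seals")
  out <- list()
  for (id in ids) {
    vf <- areas[[variable]][areas$seal_id == id]
    vo <- areas[[variable]][areas$seal_id != id]
    if (length(vf) < 2 || length(vo) == 0) next
    ref <- as.vector(abs(outer(vf, vo, "-")))
    if (reference == "within_others") {
      for (oid in setdiff(ids, id)) {
        w <- areas[[variable]][areas$seal_id == oid]
        if (length(w) >= 2) {
          M <- abs(outer(w, w, "-"))
          ref <- c(ref, M[upper.tri(M)])
        }
      }
    }
    if (length(ref) == 0) stop("empty reference set for seal ", id)
    pr <- t(utils::combn(length(vf), 2))
    d <- abs(vf[pr[, 1]] - vf[pr[, 2]])
    idx <- vapply(d, function(dd) mean(ref < dd), 0)
    out[[id]] <- list(pairs = data.frame(i = pr[, 1], j = pr[, 2],
                                         diff = d, index = idx),
                      mean_index = mean(idx))
  }
  out$summary <- data.frame(seal_id = names(out),
                            variable = variable,
                            mean_index = vapply(out, `[[`, 0, "mean_index"),
                            n_pairs = vapply(out, function(o) nrow(o$pairs), 0L),
                            stringsAsFactors = FALSE)
  rownames(out$summary) <- NULL
  out
}
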