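test_that("the forward likelihood matches exhaustive path enumeration", {
  set.seed(9)
  steps <- rgamma(8, 2, 2); ang <- runif(8, -pi, pi)
  cov <- matrix(rnorm(16), 8, 2)
  m <- fit_hmm(steps, ang, cov, n_restarts = 1, seed = 2)
  ll <- hmm_loglik(m, steps, ang, cov)
  # brute force over all 3^8 paths
  p <- m$params
  Z <- pinnitrack:::hmm_design(m, cov, 8)
  ld <- sapply(1:3, function(j)
    dgamma(steps, p$shape[j], p$rate[j], log = TRUE) +
      p$kappa[j] * cos(ang - p$mu[j]) - log(2 * pi * besselI(p$kappa[j], 0)))
  tra <- pinnitrack:::hmm_trans_array(p$tbeta, Z, 3)
  paths <- as.matrix(expand.grid(rep(list(1:3), 8)))
  lp <- apply(paths, 1, function(s) {
    acc <- log(1 / 3) + ld[1, s[1]]
    for (t in 2:8) acc <- acc + log(tra[t, s[t - 1], s[t]]) + ld[t, s[t]]
    acc
  })
  enum <- max(lp) + log(sum(exp(lp - max(lp))))
  expect_equal(ll, enum, tolerance = 1e-8)
})

test_that("identical emissions collapse to the single-state likelihood", {
  set.seed(10)
  steps <- rgamma(100, 3, 2); ang <- runif(100, -pi, pi)
  m <- fit_hmm(steps, ang, n_restarts = 1, seed = 1)
  p <- m$params
  p$shape[] <- 2; p$rate[] <- 1.5; p$kappa[] <- 0.8; p$mu[] <- 0.3
  m2 <- m; m2$params <- p
  ll <- hmm_loglik(m2, steps, ang)
  single <- sum(dgamma(steps, 2, 1.5, log = TRUE) +
                0.8 * cos(ang - 0.3) - log(2 * pi * besselI(0.8, 0)))
  expect_equal(ll, single, tolerance = 1e-6)
})

test_that("a known 3-state model is recovered by Viterbi decoding", {
  d <- sim_hmm_data(2000, 5)
  m <- fit_hmm(d$steps, d$angles, n_restarts = 3, seed = 5)
  dec <- viterbi_states(m, d$steps, d$angles)
  expect_gte(perm_accuracy(dec, d$states), 0.9)
  expect_true(is.finite(m$loglik))
})

test_that("state labelling follows the covariate and step-length rules", {
  dec <- c(1, 1, 2, 2, 3, 3, 1, 2, 3)
  steps <- c(2, 2.2, 0.3, 0.2, 0.01, 0.02, 1.9, 0.25, 0.01)
  haul <- c(0, 0, 0, 0, 0.9, 0.8, 0, 0, 0.95)
  lab <- label_states(dec, steps, haul)
  expect_equal(unname(lab[c("1", "2", "3")]),
               c("travelling", "foraging", "haulout"))
  # permuting state indices permutes the mapping, not the labels
  perm <- c(3, 1, 2)             # new index of old state
  lab2 <- label_states(perm[dec], steps, haul)
  expect_equal(unname(lab2[as.character(perm)]), unname(lab[c("1", "2", "3")]))
  # all-zero haul-out covariate still yields a (nominal) haul-out state
  expect_warning(lab3 <- label_states(dec, steps, rep(0, 9)), "haul")
  expect_setequal(unname(lab3), c("travelling", "foraging", "haulout"))
})

test_that("DBSCAN matches a density-reachability oracle", {
  set.seed(12)
  for (rep in 1:40) {
    xy <- matrix(runif(60, 0, 4), ncol = 2)
    eps <- runif(1, 0.3, 1.2); mp <- sample(3:6, 1)
    got <- dbscan_cluster(xy, eps, mp)
    D <- as.matrix(dist(xy))
    core <- rowSums(D <= eps) >= mp
    # oracle: connected components of the core-point graph
    adj <- (D <= eps) & outer(core, core, "&")
    g_lab <- integer(nrow(xy)); cl <- 0
    for (i in which(core)) {
      if (g_lab[i] != 0) next
      cl <- cl + 1
      comp <- i
      repeat {
        grow <- which(colSums(adj[comp, , drop = FALSE]) > 0 & g_lab == 0 & core)
        grow <- setdiff(grow, comp)
        if (!length(grow)) break
        comp <- c(comp, grow)
      }
      g_lab[comp] <- cl
    }
    # cores: identical partition up to relabelling
    expect_true(all((got[core] > 0)))
    expect_equal(length(unique(got[core])), length(unique(g_lab[core])))
    same_core <- outer(got[core], got[core], "==")
    same_orc <- outer(g_lab[core], g_lab[core], "==")
    expect_true(all(same_core == same_orc))
    # border points: in a cluster with a core neighbour; noise has none
    for (i in which(!core)) {
      near_cores <- which(core & D[i, ] <= eps)
      if (length(near_cores) == 0) expect_equal(got[i], 0L)
      else expect_true(got[i] %in% got[near_cores])
    }
  }
})

test_that("foraging-area selection finds the dominant cluster", {
  set.seed(2)
  big <- cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1))
  small <- cbind(rnorm(10, 10, 0.1), rnorm(10, 10, 0.1))
  fa <- select_foraging_area(rbind(big, small), min_pts = 5)
  expect_false(is.null(fa))
  expect_lte(fa$index, 20)        # member of the 20-point blob
  cen <- colMeans(big)
  expect_lt(sqrt((fa$x - cen[1])^2 + (fa$y - cen[2])^2), 0.5)
  # fewer than min_pts locations: no area
  expect_null(select_foraging_area(big[1:4, ], min_pts = 5))
})

test_that("the changepoint rule detects a mean shift and abstains on flat series", {
  set.seed(3)
  v <- c(rnorm(30, 0, 0.1), rnorm(20, 5, 0.1))
  cp <- mean_changepoint(v)
  expect_equal(cp, 31, tolerance = 1)
  expect_true(is.na(mean_changepoint(rnorm(50, 0, 0.1))))
})

test_that("similarity indices reproduce the hand-enumerated example and bounds", {
  areas <- data.frame(seal_id = c("A", "A", "B", "B", "B"),
                      v = c(10, 12, 10, 11, 30))
  r <- similarity_indices(areas, "v")
  # d = 2; cross differences {0, 1, 20, 2, 1, 18}; strictly smaller: 3/6
  expect_equal(r$A$pairs$index, 0.5)
  # a zero within-pair difference scores 0
  areas0 <- data.frame(seal_id = c("A", "A", "B", "B"), v = c(5, 5, 7, 9))
  expect_equal(similarity_indices(areas0, "v")$A$pairs$index, 0)
  # a within-pair difference above every reference difference scores 1
  areas1 <- data.frame(seal_id = c("A", "A", "B", "B"), v = c(0, 100, 49, 51))
  expect_equal(similarity_indices(areas1, "v")$A$pairs$index, 1)
  expect_error(similarity_indices(areas[areas$seal_id == "A", ], "v"),
               "at least 2")
})

test_that("similarity indices are location- and scale-invariant and bounded", {
  set.seed(13)
  areas <- data.frame(seal_id = rep(c("A", "B", "C"), each = 8),
                      v = c(rnorm(8, 5, 0.3), rnorm(8, 9, 2), rnorm(8, 7, 4)))
  r0 <- similarity_indices(areas, "v")
  for (tr in list(function(v) v + 50, function(v) v * 3)) {
    areas2 <- areas; areas2$v <- tr(areas$v)
    r2 <- similarity_indices(areas2, "v")
    expect_equal(r2$summary$mean_index, r0$summary$mean_index, tolerance = 1e-12)
  }
  all_idx <- unlist(lapply(c("A", "B", "C"), function(s) r0[[s]]$pairs$index))
  expect_true(all(all_idx >= 0 & all_idx <= 1))
  # the alternative reference set also stays in bounds
  r3 <- similarity_indices(areas, "v", reference = "within_others")
  expect_true(all(r3$summary$mean_index >= 0 & r3$summary$mean_index <= 1))
})
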