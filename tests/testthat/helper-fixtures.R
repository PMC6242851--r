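# Shared fixtures, built lazily and memoised for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# default study-condition population (4 seals, 60 days, seed 1)
default_pop <- function() memo("pop_default", function()
  simulate_population(sim_config(seed = 1)))

# a small, fast population for IO / plumbing tests
small_pop <- function() memo("pop_small", function()
  simulate_population(sim_config(n_seals = 2, duration_days = 15, seed = 42)))

tiny_env <- function() memo("env_tiny", function()
  simulate_environment(sim_config(n_seals = 2, duration_days = 10, seed = 5)))

hours_after <- function(h, origin = "2011-07-19") {
  as.POSIXct(origin, tz = "UTC") + h * 3600
}

# simulate observations from a known 3-state HMM (step gamma + wrapped
# normal angles), independent of the package's fitting code
sim_hmm_data <- function(T, seed,
                         shape = c(5, 2, 1), rate = c(2.5, 6, 20),
                         kappa = c(4, 0.5, 0.2), mu = c(0, pi, 0),
                         G = matrix(c(.92, .06, .02, .1, .85, .05, .1, .1, .8),
                                    3, 3, byrow = TRUE)) {
  set.seed(seed)
  s <- integer(T); s[1] <- 1L
  for (t in 2:T) s[t] <- sample(3, 1, prob = G[s[t - 1], ])
  steps <- rgamma(T, shape[s], rate[s])
  th <- mu[s] + rnorm(T, 0, 1 / sqrt(pmax(kappa[s], 0.01)))
  list(steps = steps, angles = atan2(sin(th), cos(th)), states = s)
}

# best state-matching accuracy over all label permutations
perm_accuracy <- function(decoded, truth, k = 3) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  max(vapply(perms, function(p) mean(p[decoded] == truth), 0))
}
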