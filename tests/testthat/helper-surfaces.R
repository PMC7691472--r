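# Small shared fixtures, memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A tiny calibration bundle for unit tests that only need a structurally
# valid envelope (not an accurate one).
tiny_surfaces <- function() {
  memo("tiny_surfaces", {
    g <- training_grid(K_levels = c(100, 600), n_reps = 2,
                       sample_times = seq(340, 1000, by = 60))
    suppressWarnings(build_surfaces(g, seed = 500))
  })
}

# Synthetic training records with a known smooth response, for exercising
# the fitting machinery without simulations.
synthetic_records <- function(n = 1200, seed = 1) {
  set.seed(seed)
  grid <- data.frame(
    metric = rep(c("Gpp_st", "phip_st"), each = n),
    mu = rep(c(5e-5, 5e-4), times = n),
    K = 100, rep = 1,
    t = 400 + rep(round(seq(10, 600, length.out = n)), 2))
  grid$T <- grid$t - 400
  grid$He <- runif(2 * n, 0.05, 0.9)
  grid$value <- pmin(1, pmax(0, 0.8 * (1 - exp(-grid$T / 150)) *
                               (1 - 0.6 * grid$He) +
                               rnorm(2 * n, 0, 0.02)))
  grid
}
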