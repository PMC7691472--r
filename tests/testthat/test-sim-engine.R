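test_that("scenario validation rejects bad fields by name", {
  expect_error(sim_scenario(K = 1), "K")
  expect_error(sim_scenario(m_before = 0.7), "m_before")
  expect_error(sim_scenario(mu = 1.5), "mu")
  expect_error(sim_scenario(t_barrier = 50, t_end = 10), "t_barrier")
  expect_error(sim_scenario(mu = c(1e-4, 1e-4)), "mu")
})

test_that("initialization is uniform over allelic states and within bounds", {
  sc <- sim_scenario(K = 1000, seed = 11)
  pops <- init_populations(sc)
  expect_equal(dim(pops[[1]]), c(1000, 30))
  states <- c(pops[[1]], pops[[2]])
  expect_true(all(states >= 1 & states <= 20))
  counts <- tabulate(states, nbins = 20)
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)

  tiny <- sim_scenario(K = 2, n_loci = 1, seed = 3)
  p <- init_populations(tiny)
  expect_equal(length(c(p[[1]], p[[2]])), 8)
  expect_true(all(unlist(p) %in% 1:20))
})

test_that("runs are bit-identical under a fixed seed", {
  sc <- sim_scenario(K = 40, t_barrier = 20, t_end = 40, seed = 99)
  s1 <- run_scenario(sc, sample_times = c(20, 40), n_sample = 10)
  s2 <- run_scenario(sc, sample_times = c(20, 40), n_sample = 10)
  expect_identical(s1, s2)
  expect_identical(init_populations(sc), init_populations(sc))
})

test_that("sampling never perturbs the evolutionary trajectory", {
  sc <- sim_scenario(K = 30, t_barrier = 10, t_end = 30, seed = 5)
  sparse <- run_scenario(sc, sample_times = 30, n_sample = 30)
  dense <- run_scenario(sc, sample_times = c(5, 10, 15, 20, 25, 30),
                        n_sample = 30)
  expect_identical(sparse[[1]]$dataset$pops$UP,
                   dense[[6]]$dataset$pops$UP)
  expect_equal(length(run_scenario(sc, sample_times = integer(0))), 0)
})

test_that("population size and allele bounds hold through the cycle", {
  sc <- sim_scenario(K = 25, n_loci = 4, n_alleles = 3, mu = 0.2,
                     m_before = 0.3, t_barrier = 15, t_end = 30, seed = 7)
  states <- init_populations(sc)
  for (t in 1:30) {
    states <- step_generation(states, sc, t)
    expect_equal(nrow(states[[1]]), 25)
    expect_equal(nrow(states[[2]]), 25)
    expect_true(all(unlist(states) >= 1 & unlist(states) <= 3))
  }
})

test_that("mutation at the boundary states reflects inward", {
  # all copies at state 1 with certain mutation: every allele becomes 2
  sc <- sim_scenario(K = 20, n_loci = 2, n_alleles = 5, mu = 0.999999,
                     m_before = 0, m_after = 0, t_barrier = 1, t_end = 2,
                     seed = 1)
  states <- list(matrix(1L, 20, 4), matrix(5L, 20, 4))
  nxt <- step_generation(states, sc, 1)
  expect_true(all(nxt[[1]] == 2L))
  expect_true(all(nxt[[2]] == 4L))
})

test_that("m = 0.5 mixes two fixed demes to ~50/50 in one generation", {
  sc <- sim_scenario(K = 1000, n_loci = 1, mu = 0, m_before = 0.5,
                     t_barrier = 10, t_end = 10, seed = 21)
  states <- list(matrix(1L, 1000, 2), matrix(2L, 1000, 2))
  set.seed(21)
  nxt <- step_generation(states, sc, 1)
  frac1 <- mean(nxt[[1]] == 1L)
  # post-migration residents are Binomial(1000, 0.5) from each source;
  # 4 sd of the offspring allele share is ~0.06
  expect_lt(abs(frac1 - 0.5), 0.06)
})

test_that("neutral drift decays heterozygosity at the closed-form rate", {
  # mu = 0, m = 0: E[H_t] = H_0 * (1 - 1/(2K))^t for the unbiased
  # whole-deme gene diversity
  K <- 20
  t_max <- 40
  n_rep <- 30
  h_of <- function(mat) {
    L <- ncol(mat) / 2
    mean(vapply(seq_len(L), function(l) {
      p <- tabulate(mat[, c(2 * l - 1, 2 * l)], nbins = 20) / (2 * K)
      (2 * K / (2 * K - 1)) * (1 - sum(p^2))
    }, numeric(1)))
  }
  set.seed(404)
  h0 <- ht <- numeric(0)
  sc <- sim_scenario(K = K, mu = 0, m_before = 0, m_after = 0,
                     t_barrier = 1, t_end = t_max)
  for (r in seq_len(n_rep)) {
    states <- init_populations(sc)
    h0 <- c(h0, h_of(states[[1]]), h_of(states[[2]]))
    for (t in seq_len(t_max)) states <- step_generation(states, sc, t)
    ht <- c(ht, h_of(states[[1]]), h_of(states[[2]]))
  }
  expected_ratio <- (1 - 1 / (2 * K))^t_max
  expect_lt(abs(mean(ht) / mean(h0) - expected_ratio), 0.05)
})

test_that("without migration the demes evolve independently", {
  # two demes started from a common state but with m = 0 diverge; with no
  # mutation each small deme eventually fixes (heterozygosity hits 0)
  sc <- sim_scenario(K = 10, n_loci = 5, mu = 0, m_before = 0, m_after = 0,
                     t_barrier = 1, t_end = 400, seed = 31)
  s <- run_scenario(sc, sample_times = 400, n_sample = 10)
  pops <- s[[1]]$dataset$pops
  fixed_per_locus <- function(mat) {
    vapply(1:5, function(l)
      length(unique(c(mat[, 2 * l - 1], mat[, 2 * l]))) == 1, logical(1))
  }
  expect_true(all(fixed_per_locus(pops$UP)))
  expect_true(all(fixed_per_locus(pops$DOWN)))
})

test_that("an empty post-migration deme aborts with an explicit error", {
  # K = 2 and m = 0.5: P(a deme empties) ~ 1/8 per generation, so a long
  # fixed-seed run is guaranteed to hit the condition
  sc <- sim_scenario(K = 2, n_loci = 1, mu = 0, m_before = 0.5,
                     m_after = 0.5, t_barrier = 5000, t_end = 5000,
                     seed = 17)
  expect_error(run_scenario(sc, sample_times = integer(0), n_sample = 2),
               "empty deme")
})

test_that("sampling constraints are enforced", {
  sc <- sim_scenario(K = 10, t_barrier = 2, t_end = 5, seed = 1)
  expect_error(run_scenario(sc, sample_times = 5, n_sample = 11),
               "n_sample")
  expect_error(run_scenario(sc, sample_times = 9), "sample_times")
})

test_that("lognormal locus mutation rates hit their bounds and mean", {
  r <- draw_locus_mutation_rates(15, seed = 8)
  expect_length(r, 15)
  expect_true(all(r >= 5e-5 & r <= 5e-3))
  expect_identical(r, draw_locus_mutation_rates(15, seed = 8))

  big <- draw_locus_mutation_rates(1e5, seed = 9)
  expect_lt(abs(mean(big) / 5e-4 - 1), 0.05)

  expect_error(draw_locus_mutation_rates(5, low = 1e-3, high = 2e-3,
                                         mean = 5e-4), "infeasible")
})
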