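fixed_pair <- function(a1, a2, n = 6, L = 2) {
  pops <- list(A = matrix(a1, n, 2 * L), B = matrix(a2, n, 2 * L))
  genotype_dataset(pops, sprintf("L%d", 1:L))
}

test_that("expected heterozygosity matches direct arithmetic", {
  # one locus, n = 10, two alleles at 0.5/0.5 -> (20/19)(1 - 0.5)
  m <- matrix(rep(c(1L, 2L), 10), 10, byrow = TRUE)
  he <- expected_heterozygosity(genotype_dataset(list(A = m), "L1"))
  expect_equal(he$He_mean, (20 / 19) * 0.5, tolerance = 1e-12)

  mono <- expected_heterozygosity(fixed_pair(1L, 1L))
  expect_equal(mono$He_mean, 0)

  # He_mean is the arithmetic mean of the per-population averages
  ds <- random_toy_dataset(42, p_missing = 0)
  he2 <- expected_heterozygosity(ds)
  expect_equal(he2$He_mean, mean(he2$per_pop), tolerance = 1e-12)
  expect_true(all(he2$per_locus >= 0 & he2$per_locus < 1))
})

test_that("reciprocally fixed populations give maximal differentiation", {
  ds <- fixed_pair(1L, 2L)
  expect_equal(hedrick_gpp_st(ds), 1, tolerance = 1e-12)
  expect_equal(meirmans_phi_prime_st(ds), 1, tolerance = 1e-12)
})

test_that("identical populations clamp to zero differentiation", {
  set.seed(10)
  m <- matrix(sample.int(4, 8 * 4, TRUE), 8)
  ds <- genotype_dataset(list(A = m, B = m), c("L1", "L2"))
  expect_equal(hedrick_gpp_st(ds), 0)
  expect_equal(meirmans_phi_prime_st(ds), 0)
  mono <- fixed_pair(3L, 3L)
  expect_equal(hedrick_gpp_st(mono), 0)
})

test_that("both metrics match brute-force oracles on randomized datasets", {
  for (seed in 1:25) {
    ds <- random_toy_dataset(seed)
    expect_equal(suppressWarnings(hedrick_gpp_st(ds)), oracle_gpp_st(ds$pops),
                 tolerance = 1e-10, label = paste("G''st seed", seed))
    expect_equal(meirmans_phi_prime_st(ds), oracle_phip_st(ds$pops),
                 tolerance = 1e-10, label = paste("phi'st seed", seed))
  }
})

test_that("metrics are invariant to allele relabeling and population swap", {
  for (seed in c(3, 14, 27)) {
    ds <- random_toy_dataset(seed, p_missing = 0)
    g0 <- hedrick_gpp_st(ds)
    p0 <- meirmans_phi_prime_st(ds)

    perm <- sample(10)  # relabel states 1..4 injectively
    relab <- lapply(ds$pops, function(m) {
      m[] <- perm[m]
      m
    })
    ds_r <- genotype_dataset(relab, ds$loci)
    expect_equal(hedrick_gpp_st(ds_r), g0, tolerance = 1e-12)
    expect_equal(meirmans_phi_prime_st(ds_r), p0, tolerance = 1e-12)

    ds_s <- genotype_dataset(ds$pops[c(2, 1)], ds$loci)
    expect_equal(hedrick_gpp_st(ds_s), g0, tolerance = 1e-12)
    expect_equal(meirmans_phi_prime_st(ds_s), p0, tolerance = 1e-12)
  }
})

test_that("clamped metrics stay within [0, 1] on random data", {
  for (seed in 26:45) {
    ds <- random_toy_dataset(seed)
    g <- suppressWarnings(hedrick_gpp_st(ds))
    p <- meirmans_phi_prime_st(ds)
    if (!is.na(g)) expect_true(g >= 0 && g <= 1 + 1e-12)
    if (!is.na(p)) expect_true(p >= 0 && p <= 1 + 1e-12)
  }
})

test_that("diff_stats agrees with the standalone estimators", {
  ds <- random_toy_dataset(77, p_missing = 0)
  st <- diff_stats(ds)
  expect_equal(st$Gpp_st, hedrick_gpp_st(ds), tolerance = 1e-12)
  expect_equal(st$phip_st, meirmans_phi_prime_st(ds), tolerance = 1e-12)
  expect_equal(st$He_mean, expected_heterozygosity(ds)$He_mean,
               tolerance = 1e-12)
})

test_that("loci missing in one population are dropped with a warning", {
  ds <- random_toy_dataset(5, p_missing = 0)
  pops <- ds$pops
  pops$A[, 1:2] <- NA_integer_  # locus 1 unscored in population A
  ds2 <- genotype_dataset(pops, ds$loci)
  expect_warning(hedrick_gpp_st(ds2), "dropped")
  if (length(ds$loci) > 1) {
    sub <- genotype_dataset(lapply(pops, function(m) m[, -(1:2), drop = FALSE]),
                            ds$loci[-1])
    expect_equal(suppressWarnings(hedrick_gpp_st(ds2)),
                 hedrick_gpp_st(sub), tolerance = 1e-12)
  }
})

test_that("pairwise estimators refuse non-pairwise input", {
  ds <- random_toy_dataset(6)
  three <- genotype_dataset(c(ds$pops, list(C = ds$pops$A)), ds$loci)
  expect_error(hedrick_gpp_st(three), "2 populations")
  expect_error(meirmans_phi_prime_st(three), "2 populations")
})

test_that("sustained full mixing keeps differentiation near zero", {
  # K = 250, m = 0.5 throughout; metrics on the (nearly) complete demes so
  # the check reflects the demes themselves, not 30-genotype sampling noise
  vals <- c()
  for (seed in 1:10) {
    sc <- sim_scenario(K = 250, m_before = 0.5, m_after = 0.5,
                       t_barrier = 200, t_end = 200, seed = seed)
    s <- run_scenario(sc, sample_times = 200, n_sample = 250)
    st <- diff_stats(s[[1]]$dataset)
    vals <- c(vals, st$Gpp_st, st$phip_st)
  }
  expect_true(mean(vals < 0.01) >= 0.95)
  expect_lt(median(vals), 0.005)
})
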