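test_that("the index anchors at 0 and 100 and matches direct arithmetic", {
  expect_equal(as.numeric(findex_single(0.001, 0.001, 0.5)), 0)
  expect_equal(as.numeric(findex_single(0.5, 0.001, 0.5)), 100)
  f <- findex_single(0.05, 0.001, 0.5)
  expect_equal(as.numeric(f),
               100 * (log(0.001) - log(0.05)) / (log(0.001) - log(0.5)),
               tolerance = 1e-12)
  expect_equal(as.numeric(f), 62.95, tolerance = 0.01)
  expect_false(attr(f, "clamped"))
})

test_that("observations outside the envelope clamp and are flagged", {
  z <- findex_single(0, 0.001, 0.5)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "clamped"))
  lo <- findex_single(0.0005, 0.001, 0.5)
  expect_equal(as.numeric(lo), 0)
  hi <- findex_single(0.9, 0.001, 0.5)
  expect_equal(as.numeric(hi), 100)
  expect_true(attr(hi, "clamped"))
})

test_that("the index is strictly increasing inside the envelope", {
  obs <- seq(0.002, 0.49, length.out = 50)
  f <- as.numeric(findex_single(obs, 0.001, 0.5))
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 100))
})

test_that("degenerate envelopes are rejected", {
  expect_error(findex_single(0.1, 0, 0.5), "gd_min")
  expect_error(findex_single(0.1, 0.5, 0.5), "invalid surfaces")
  expect_error(findex_single(0.1, 0.5, 0.2), "invalid surfaces")
  expect_error(findex_single(-0.1, 0.001, 0.5), "gd_obs")
})

test_that("averaging follows the published SE rule", {
  fm <- findex_mean(c(50, 60, 55, 45))
  expect_equal(fm$mean, 52.5)
  expect_equal(fm$ci95, 1.96 * sd(c(50, 60, 55, 45)) / 4, tolerance = 1e-12)
  expect_equal(fm$ci95, 3.163, tolerance = 1e-3)

  conv <- findex_mean(c(50, 60, 55, 45), se_rule = "conventional")
  expect_equal(conv$ci95, 1.96 * sd(c(50, 60, 55, 45)) / 2, tolerance = 1e-12)

  expect_equal(findex_mean(rep(62.2, 4))$ci95, 0)
  zero <- findex_mean(rep(0, 4))
  expect_equal(zero$mean, 0)
  expect_equal(zero$ci95, 0)

  dropped <- findex_mean(c(50, NA, 60, NA))
  expect_equal(dropped$mean, 55)
  expect_equal(dropped$n_dropped, 2)
  one <- findex_mean(c(40, NA, NA, NA))
  expect_true(is.na(one$ci95))
  expect_error(findex_mean(c(NA_real_, NA_real_)), "no valid")
})

test_that("the overall index matches the closed-form REML oracle", {
  # balanced two-group synthetic data with real between-group variance
  set.seed(2024)
  y <- c(rnorm(4, 50, 3), rnorm(4, 70, 3))
  g <- rep(c("a", "b"), each = 4)
  ov <- findex_overall(y, g)
  oracle <- oracle_balanced_reml(y, g)
  expect_equal(ov$estimate, oracle$intercept, tolerance = 1e-6)
  expect_equal(ov$se, oracle$se, tolerance = 1e-6)
  expect_equal(ov$ci95, 1.96 * oracle$se, tolerance = 1e-6)
  expect_false(ov$singular)

  # balanced design: intercept equals the mean of dataset means
  y2 <- c(10, 20, 30, 42, 52, 62)
  ov2 <- findex_overall(y2, rep(c("a", "b"), each = 3))
  expect_equal(ov2$estimate, mean(c(mean(y2[1:3]), mean(y2[4:6]))),
               tolerance = 1e-6)

  # identical datasets: degenerate variance handled, estimate = common mean
  y3 <- rep(c(40, 50, 60, 70), 2)
  ov3 <- findex_overall(y3, rep(c("a", "b"), each = 4))
  expect_equal(ov3$estimate, 55, tolerance = 1e-8)
  expect_true(ov3$singular)

  # single dataset falls back to the plain mean
  ov4 <- findex_overall(c(50, 60, 55, 45), rep("only", 4))
  expect_equal(ov4$estimate, 52.5)
  expect_equal(ov4$ci95, findex_mean(c(50, 60, 55, 45))$ci95)
})

test_that("obstacle scoring separates total barriers from full mixing", {
  surf <- tiny_surfaces()
  barrier <- sim_scenario(K = 100, m_after = 0, seed = 61)
  sb <- run_scenario(barrier, sample_times = 700)
  rb <- compute_for_obstacle(sb[[1]]$dataset, "UP", "DOWN", T = 300,
                             surfaces = surf)
  expect_s3_class(rb, "findex_result")
  expect_gt(rb$findex + rb$ci95, 90)

  open <- sim_scenario(K = 100, m_after = 0.5, seed = 62)
  so <- run_scenario(open, sample_times = 700)
  ro <- compute_for_obstacle(so[[1]]$dataset, "UP", "DOWN", T = 300,
                             surfaces = surf)
  expect_lt(ro$findex - ro$ci95, 20)
  expect_gt(rb$findex, ro$findex)
})

test_that("a copied population scores exactly zero", {
  set.seed(9)
  m <- matrix(sample.int(12, 30 * 2 * 5, TRUE), 30)
  ds <- genotype_dataset(list(UP = m, DOWN = m), sprintf("L%d", 1:5))
  r <- compute_for_obstacle(ds, "UP", "DOWN", T = 50,
                            surfaces = tiny_surfaces())
  expect_equal(r$findex, 0)
  expect_true("index_clamped" %in% r$flags)
})

test_that("obstacle scoring validates inputs and warns for young barriers", {
  surf <- tiny_surfaces()
  sc <- sim_scenario(K = 50, t_barrier = 10, t_end = 20, seed = 3)
  ds <- run_scenario(sc, sample_times = 20)[[1]]$dataset
  expect_error(compute_for_obstacle(ds, "UP", "NOPE", 50, surf),
               "available")
  expect_error(compute_for_obstacle(ds, "UP", "DOWN", 0.5, surf), "T")
  expect_warning(r <- compute_for_obstacle(ds, "UP", "DOWN", 5, surf),
                 "background noise")
  expect_true("T_below_10" %in% r$flags)
  expect_error(compute_for_obstacle(ds, "UP", "DOWN", 50), "surfaces")
})

test_that("a user-supplied envelope bypasses the surfaces", {
  sc <- sim_scenario(K = 50, seed = 8)
  ds <- run_scenario(sc, sample_times = 700)[[1]]$dataset
  gd <- data.frame(metric = rep(c("Gpp_st", "phip_st"), 2),
                   mu = rep(c(5e-5, 5e-4), each = 2),
                   gd_min = 0.001, gd_max = 0.9)
  r <- compute_for_obstacle(ds, "UP", "DOWN", T = 300, user_gd = gd)
  expect_true("user_envelope" %in% r$flags)
  st <- diff_stats(subset_populations(ds, c("UP", "DOWN")))
  expect_equal(r$table$gd_obs[r$table$metric == "Gpp_st"][1], st$Gpp_st)
  manual <- as.numeric(findex_single(st$Gpp_st, 0.001, 0.9))
  expect_equal(r$table$index[r$table$metric == "Gpp_st"][1], manual,
               tolerance = 1e-10)
})
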