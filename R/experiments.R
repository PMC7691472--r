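#' Define a validation grid
#'
#' Describes the set of scenarios used to check that the index tracks the
#' true permeability of a simulated obstacle: two demes mixing at `m = 0.5`
#' for 400 generations, then crossing the obstacle at rate `m`, with
#' heterogeneous per-locus mutation rates drawn from the truncated
#' lognormal of [draw_locus_mutation_rates()] (fresh draw per replicate).
#'
#' @param K_levels carrying capacities.
#' @param m_levels post-barrier crossing rates.
#' @param sample_times generations sampled (barrier ages are
#'   `sample_times - 400`).
#' @param n_reps replicates per (K, m) cell.
#' @param n_loci,n_alleles,n_sample,t_barrier,t_end scenario constants.
#' @return a list of class `validation_grid`.
#' @export
validation_grid <- function(K_levels = c(50, 100, 250, 500, 1000),
                            m_levels = c(seq(0, 0.2, by = 0.01),
                                         seq(0.25, 0.5, by = 0.05)),
                            sample_times = c(405, 410, 415, 420, 425,
                                             450, 500, 700),
                            n_reps = 20, n_loci = 15, n_alleles = 20,
                            n_sample = 30, t_barrier = 400, t_end = 1000) {
  structure(list(K_levels = as.integer(K_levels), m_levels = m_levels,
                 sample_times = as.integer(sample_times),
                 n_reps = as.integer(n_reps), n_loci = as.integer(n_loci),
                 n_alleles = as.integer(n_alleles),
                 n_sample = as.integer(n_sample),
                 t_barrier = as.integer(t_barrier),
                 t_end = as.integer(t_end)),
            class = "validation_grid")
}

#' Desk-scale validation preset
#'
#' Three carrying capacities, six crossing rates spanning total barrier to
#' full connectivity, three sampling ages and three replicates: enough to
#' probe every qualitative behaviour of the index in a few minutes.
#'
#' @return a [validation_grid()].
#' @export
validation_grid_desk <- function() {
  validation_grid(K_levels = c(50, 250, 1000),
                  m_levels = c(0, 0.01, 0.05, 0.1, 0.2, 0.5),
                  sample_times = c(415, 450, 700), n_reps = 3)
}

#' Number of simulated datasets a validation grid will produce
#'
#' Pure accounting, no simulation: cells x sampling times x replicates.
#'
#' @param grid a [validation_grid()].
#' @return integer count of sampled datasets.
#' @export
validation_grid_size <- function(grid) {
  stopifnot(inherits(grid, "validation_grid"))
  length(grid$K_levels) * length(grid$m_levels) *
    length(grid$sample_times) * grid$n_reps
}

#' Run the validation harness
#'
#' For every (K, m, replicate) cell: simulate the scenario, sample the two
#' demes at each grid sampling time, compute the observed differentiation
#' and heterozygosity, score the four sub-indices against the calibration
#' surfaces, and aggregate replicates per (K, m, T) cell with the
#' intercept-only mixed model. Deterministic given `seed`.
#'
#' @param grid a [validation_grid()].
#' @param surfaces a `findex_surfaces` bundle.
#' @param seed master integer seed.
#' @param progress print one line per simulation run.
#' @return a list with `records` (one row per dataset x metric x
#'   calibration mu: `K`, `m`, `rep`, `t`, `T`, `He`, `metric`, `mu`,
#'   `gd_obs`, `gd_min`, `gd_max`, `index`) and `cells` (per (K, m, T):
#'   `findex`, `ci95`, `n_datasets`, `singular`).
#' @export
run_validation <- function(grid, surfaces, seed = 1, progress = FALSE) {
  stopifnot(inherits(grid, "validation_grid"),
            inherits(surfaces, "findex_surfaces"))
  runs <- expand.grid(K = grid$K_levels, m = grid$m_levels,
                      rep = seq_len(grid$n_reps), KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  runs$seed <- sample.int(.Machine$integer.max, nrow(runs))
  rec <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    mu <- draw_locus_mutation_rates(grid$n_loci, seed = runs$seed[i])
    sc <- sim_scenario(K = runs$K[i], n_loci = grid$n_loci,
                       n_alleles = grid$n_alleles, mu = mu,
                       m_before = 0.5, m_after = runs$m[i],
                       t_barrier = grid$t_barrier, t_end = grid$t_end,
                       seed = runs$seed[i] %% .Machine$integer.max + 1)
    samples <- run_scenario(sc, grid$sample_times, grid$n_sample)
    rec[[i]] <- do.call(rbind, lapply(samples, function(s) {
      st <- diff_stats(s$dataset)
      score_measurement(surfaces, T_val = s$T, He = st$He_mean,
                        gd_obs = c(Gpp_st = max(0, st$Gpp_st),
                                   phip_st = max(0, st$phip_st)),
                        base = data.frame(K = runs$K[i], m = runs$m[i],
                                          rep = runs$rep[i], t = s$t,
                                          T = s$T))
    }))
    if (progress)
      message(sprintf("run %d/%d (K=%d, m=%g, rep=%d) done",
                      i, nrow(runs), runs$K[i], runs$m[i], runs$rep[i]))
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  list(records = records, cells = aggregate_validation(records))
}

# score one sampled dataset against the four surfaces
score_measurement <- function(surfaces, T_val, He, gd_obs, base) {
  env <- suppressWarnings(predict_gd_max(surfaces, T = T_val, He = He))
  env$gd_obs <- unname(gd_obs[env$metric])
  idx <- vapply(seq_len(nrow(env)), function(j) {
    if (is.na(env$gd_obs[j])) return(NA_real_)
    as.numeric(findex_single(env$gd_obs[j], env$gd_min[j], env$gd_max[j]))
  }, numeric(1))
  cbind(base[rep(1, nrow(env)), , drop = FALSE],
        data.frame(He = He, metric = env$metric, mu = env$mu,
                   gd_obs = env$gd_obs, gd_min = env$gd_min,
                   gd_max = env$gd_max, index = idx))
}

#' Aggregate validation records per (K, m, T) cell
#'
#' @param records the `records` table from [run_validation()].
#' @return data.frame with one row per (K, m, T): mixed-model `findex`,
#'   `ci95`, `n_datasets`, `singular`.
#' @export
aggregate_validation <- function(records) {
  cells <- unique(records[, c("K", "m", "T")])
  cells <- cells[order(cells$K, cells$m, cells$T), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    r <- records[records$K == cells$K[i] & records$m == cells$m[i] &
                   records$T == cells$T[i] & !is.na(records$index), ]
    ov <- findex_overall(r$index, r$rep)
    data.frame(K = cells$K[i], m = cells$m[i], T = cells$T[i],
               findex = ov$estimate, ci95 = ov$ci95,
               n_datasets = ov$n_datasets, singular = ov$singular)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sensitivity of the index to uncertainty in barrier age
#'
#' Re-scores already-simulated validation records after multiplying the
#' barrier age fed to the surfaces by each perturbation factor (the
#' simulated data themselves are untouched, mimicking a user who
#' mis-estimates generation time). Factor 1 reproduces the original
#' indices exactly.
#'
#' @param records the `records` table from [run_validation()].
#' @param surfaces the same `findex_surfaces` bundle.
#' @param factors multiplicative perturbations of `T`.
#' @return data.frame: per (K, m, T, factor), the mean index over
#'   replicates and metrics.
#' @export
sensitivity_T <- function(records, surfaces, factors = c(0.5, 1, 1.5)) {
  base <- unique(records[, c("K", "m", "rep", "t", "T", "He", "metric",
                             "gd_obs")])
  out <- list()
  for (f in factors) {
    idx <- numeric(nrow(base))
    for (i in seq_len(nrow(base))) {
      env <- suppressWarnings(
        predict_gd_max(surfaces, T = max(base$T[i] * f, 1e-9),
                       He = base$He[i]))
      env <- env[env$metric == base$metric[i], ]
      vals <- vapply(seq_len(nrow(env)), function(j)
        as.numeric(findex_single(base$gd_obs[i], env$gd_min[j],
                                 env$gd_max[j])), numeric(1))
      idx[i] <- mean(vals)
    }
    agg <- aggregate(idx, by = base[, c("K", "m", "T")], FUN = mean)
    names(agg)[4] <- "mean_index"
    agg$factor <- f
    out[[as.character(f)]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sensitivity of the index to the number of markers
#'
#' Simulates a small set of scenarios, then re-computes differentiation and
#' the index after subsampling the locus panel (seeded, without
#' replacement), quantifying the cost of genotyping fewer microsatellites.
#'
#' @param grid a [validation_grid()] (kept small).
#' @param surfaces a `findex_surfaces` bundle.
#' @param n_loci_list locus panel sizes to evaluate; values equal to the
#'   grid's panel reproduce the full-panel index.
#' @param seed integer seed (simulation and locus subsampling).
#' @return data.frame: per (K, m, T, n_loci), mean index over replicates.
#' @export
sensitivity_markers <- function(grid, surfaces, n_loci_list = c(15, 10, 5),
                                seed = 1) {
  stopifnot(inherits(grid, "validation_grid"))
  runs <- expand.grid(K = grid$K_levels, m = grid$m_levels,
                      rep = seq_len(grid$n_reps), KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  runs$seed <- sample.int(.Machine$integer.max, nrow(runs))
  out <- list()
  for (i in seq_len(nrow(runs))) {
    mu <- draw_locus_mutation_rates(grid$n_loci, seed = runs$seed[i])
    sc <- sim_scenario(K = runs$K[i], n_loci = grid$n_loci,
                       n_alleles = grid$n_alleles, mu = mu,
                       m_before = 0.5, m_after = runs$m[i],
                       t_barrier = grid$t_barrier, t_end = grid$t_end,
                       seed = runs$seed[i] %% .Machine$integer.max + 1)
    samples <- run_scenario(sc, grid$sample_times, grid$n_sample)
    set.seed(runs$seed[i])
    for (nl in n_loci_list) {
      keep <- sort(sample.int(grid$n_loci, nl))
      cols <- as.vector(rbind(2 * keep - 1, 2 * keep))
      for (s in samples) {
        sub <- genotype_dataset(lapply(s$dataset$pops,
                                       function(p) p[, cols, drop = FALSE]),
                                s$dataset$loci[keep])
        st <- diff_stats(sub)
        sm <- score_measurement(
          surfaces, T_val = s$T, He = st$He_mean,
          gd_obs = c(Gpp_st = max(0, st$Gpp_st),
                     phip_st = max(0, st$phip_st)),
          base = data.frame(K = runs$K[i], m = runs$m[i], rep = runs$rep[i],
                            t = s$t, T = s$T))
        sm$n_loci <- nl
        out[[length(out) + 1]] <- sm
      }
    }
  }
  rec <- do.call(rbind, out)
  agg <- aggregate(rec$index, by = rec[, c("K", "m", "T", "n_loci")],
                   FUN = mean, na.rm = TRUE)
  names(agg)[5] <- "mean_index"
  rownames(agg) <- NULL
  agg
}
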