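SURFACES_VERSION <- "1.0"

#' Define a calibration training grid
#'
#' Describes the set of two-deme scenarios simulated to calibrate the
#' no-barrier floor `GD_min` and the total-barrier ceiling `GD_max`. Each
#' grid cell is one scenario with `m = 0.5` up to `t_barrier` generations
#' (no barrier) and `m = 0` afterwards (total barrier); genotypes are
#' sampled at `sample_times` and both differentiation metrics plus mean
#' heterozygosity are recorded. Records with barrier age `T <= 0` feed the
#' `GD_min` percentile, records with `T > 0` feed the `GD_max` random
#' forest.
#'
#' @param K_levels carrying capacities simulated.
#' @param mu_levels stepwise mutation rates (one calibration surface is fit
#'   per metric x mutation-rate combination).
#' @param n_reps simulation replicates per (K, mu) cell.
#' @param sample_times generations at which 30-genotype samples are taken.
#' @param n_loci,n_alleles,n_sample,t_barrier,t_end scenario constants.
#' @return a list of class `training_grid`.
#' @export
training_grid <- function(K_levels = round(seq(30, 2000, length.out = 93)),
                          mu_levels = c(5e-5, 5e-4), n_reps = 10,
                          sample_times = seq(300, 1000, by = 10),
                          n_loci = 15, n_alleles = 20, n_sample = 30,
                          t_barrier = 400, t_end = 1000) {
  structure(list(K_levels = as.integer(K_levels), mu_levels = mu_levels,
                 n_reps = as.integer(n_reps),
                 sample_times = as.integer(sample_times),
                 n_loci = as.integer(n_loci), n_alleles = as.integer(n_alleles),
                 n_sample = as.integer(n_sample),
                 t_barrier = as.integer(t_barrier), t_end = as.integer(t_end)),
            class = "training_grid")
}

#' Reduced (desk-scale) training grid
#'
#' The same 93-level linear carrying-capacity ladder as
#' [training_grid_paper()] but with two replicates per cell instead of ten:
#' a pure replication reduction (26,412 sampled datasets per metric instead
#' of 132,060) that preserves the K-weighting of the training records, and
#' with it the variance structure the surfaces are fit to. Trainable in a
#' few minutes on one core; this is the default grid of [findex_train()]
#' and of the package tests.
#'
#' @return a [training_grid()].
#' @export
training_grid_reduced <- function() {
  training_grid(n_reps = 2)
}

#' Full-scale training grid
#'
#' 93 carrying-capacity levels spaced linearly from 30 to 2000 (step 21.41)
#' with ten replicates: 93 x 2 x 10 runs x 71 sampling times = 132,060
#' sampled datasets per metric. The linear ladder concentrates most
#' training mass at moderate-to-large K, where the differentiation metrics
#' are well behaved; the handful of sub-130 levels anchor the low-He corner
#' of the surface.
#'
#' @return a [training_grid()].
#' @export
training_grid_paper <- function() {
  training_grid(n_reps = 10)
}

#' Simulate the calibration training set
#'
#' Runs every (K, mu, replicate) cell of a [training_grid()] and records,
#' for each sampled generation, one row per differentiation metric with the
#' metric value (negatives clamped to 0), the mean expected heterozygosity,
#' and the cell descriptors. Fully deterministic given `seed`; per-cell
#' checkpoints allow interrupted grids to resume.
#'
#' @param grid a [training_grid()].
#' @param seed master integer seed; per-cell seeds are derived from it.
#' @param checkpoint_dir optional directory for per-cell checkpoint files
#'   (`.rds`); existing checkpoints are reused.
#' @param progress print one line per cell.
#' @return a data.frame with columns `metric`, `value`, `mu`, `K`, `rep`,
#'   `t`, `T`, `He`.
#' @export
generate_training_set <- function(grid, seed = 1, checkpoint_dir = NULL,
                                  progress = FALSE) {
  stopifnot(inherits(grid, "training_grid"))
  cells <- expand.grid(K = grid$K_levels, mu = grid$mu_levels,
                       rep = seq_len(grid$n_reps), KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  cells$seed <- sample.int(.Machine$integer.max, nrow(cells))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ck <- NULL
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      ck <- file.path(checkpoint_dir,
                      sprintf("cell_K%d_mu%g_rep%d.rds",
                              cells$K[i], cells$mu[i], cells$rep[i]))
      if (file.exists(ck)) { out[[i]] <- readRDS(ck); next }
    }
    sc <- sim_scenario(K = cells$K[i], n_loci = grid$n_loci,
                       n_alleles = grid$n_alleles, mu = cells$mu[i],
                       m_before = 0.5, m_after = 0,
                       t_barrier = grid$t_barrier, t_end = grid$t_end,
                       seed = cells$seed[i])
    samples <- run_scenario(sc, grid$sample_times, grid$n_sample)
    rows <- lapply(samples, function(s) {
      st <- diff_stats(s$dataset)
      data.frame(metric = c("Gpp_st", "phip_st"),
                 value = pmax(0, c(st$Gpp_st, st$phip_st)),
                 mu = cells$mu[i], K = cells$K[i], rep = cells$rep[i],
                 t = s$t, T = s$T, He = st$He_mean)
    })
    out[[i]] <- do.call(rbind, rows)
    if (!is.null(ck)) saveRDS(out[[i]], ck)
    if (progress)
      message(sprintf("cell %d/%d (K=%d, mu=%g, rep=%d) done",
                      i, nrow(cells), cells$K[i], cells$mu[i], cells$rep[i]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' No-barrier floor: 5th percentile of non-null pre-barrier differentiation
#'
#' For each metric x mutation-rate combination, takes the records generated
#' before barrier creation (`T <= 0`, i.e. under sustained `m = 0.5`), drops
#' exact zeros, and returns the 5th percentile of the remaining values: the
#' background differentiation attributable to drift, mutation and finite
#' sampling alone.
#'
#' @param records training records from [generate_training_set()].
#' @return data.frame with columns `metric`, `mu`, `gd_min`, `n_records`.
#' @export
estimate_gd_min <- function(records) {
  pre <- records[records$T <= 0, , drop = FALSE]
  if (!nrow(pre)) stop("no pre-barrier (T <= 0) records")
  combos <- unique(pre[, c("metric", "mu")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    v <- pre$value[pre$metric == combos$metric[i] & pre$mu == combos$mu[i]]
    if (length(v) < 100)
      warning("fewer than 100 pre-barrier records for ", combos$metric[i],
              ", mu=", combos$mu[i], "; GD_min estimate will be noisy")
    v <- v[v > 0]
    if (!length(v))
      stop("no non-null pre-barrier values for ", combos$metric[i],
           ", mu=", combos$mu[i])
    data.frame(metric = combos$metric[i], mu = combos$mu[i],
               gd_min = unname(quantile(v, 0.05)), n_records = length(v))
  })
  do.call(rbind, out)
}

#' Total-barrier ceiling: random-forest GD ~ T, He surfaces
#'
#' For each metric x mutation-rate combination, fits a random-forest
#' regression of the post-barrier (`T > 0`) differentiation value on the
#' barrier age `T` and the mean expected heterozygosity `He` (200 trees,
#' per-tree bootstrap samples of 500 records). Out-of-bag explained
#' variance and mean squared error are recorded for each fit.
#'
#' @param records training records from [generate_training_set()].
#' @param ntree number of trees.
#' @param sampsize per-tree bootstrap sample size (shrunk with a warning if
#'   the training set is smaller).
#' @param seed integer seed for the forest fits.
#' @return list with `models` (named list of randomForest objects, keys
#'   `"<metric>|mu=<mu>"`) and `fit_stats` (data.frame with OOB statistics).
#' @export
fit_gd_max <- function(records, ntree = 200, sampsize = 500, seed = 1) {
  post <- records[records$T > 0, , drop = FALSE]
  if (!nrow(post)) stop("no post-barrier (T > 0) records")
  combos <- unique(post[, c("metric", "mu")])
  models <- list()
  stats <- list()
  set.seed(seed)
  for (i in seq_len(nrow(combos))) {
    d <- post[post$metric == combos$metric[i] & post$mu == combos$mu[i],
              c("value", "T", "He")]
    ss <- sampsize
    if (nrow(d) < sampsize) {
      warning("fewer than ", sampsize, " training records for ",
              combos$metric[i], ", mu=", combos$mu[i],
              "; per-tree sample shrunk to ", nrow(d))
      ss <- nrow(d)
    }
    rf <- randomForest::randomForest(value ~ T + He, data = d,
                                     ntree = ntree, sampsize = ss,
                                     replace = TRUE)
    key <- surface_key(combos$metric[i], combos$mu[i])
    models[[key]] <- rf
    resub <- predict(rf, d)
    stats[[key]] <- data.frame(
      metric = combos$metric[i], mu = combos$mu[i], n_records = nrow(d),
      oob_var_explained = 100 * rf$rsq[ntree],
      oob_mse = rf$mse[ntree],
      resub_r2 = 1 - mean((resub - d$value)^2) / var(d$value))
  }
  list(models = models, fit_stats = do.call(rbind, stats))
}

surface_key <- function(metric, mu) sprintf("%s|mu=%g", metric, mu)

#' Build the full calibration bundle
#'
#' Convenience pipeline: [generate_training_set()], [estimate_gd_min()],
#' [fit_gd_max()], assembled into a versioned `findex_surfaces` object.
#'
#' @param grid a [training_grid()]; default [training_grid_reduced()].
#' @param seed master seed for simulations and forest fits.
#' @param checkpoint_dir passed to [generate_training_set()].
#' @param progress passed to [generate_training_set()].
#' @return an object of class `findex_surfaces` with elements `gd_min`,
#'   `models`, `fit_stats`, `grid`, `seed`, `he_domain`, `t_domain`.
#' @export
build_surfaces <- function(grid = training_grid_reduced(), seed = 1,
                           checkpoint_dir = NULL, progress = FALSE) {
  records <- generate_training_set(grid, seed = seed,
                                   checkpoint_dir = checkpoint_dir,
                                   progress = progress)
  gd_min <- estimate_gd_min(records)
  fit <- fit_gd_max(records, seed = seed)
  structure(list(version = SURFACES_VERSION, gd_min = gd_min,
                 models = fit$models, fit_stats = fit$fit_stats,
                 grid = grid, seed = seed,
                 he_domain = c(0, 0.93),
                 t_domain = c(0, max(records$T))),
            class = "findex_surfaces")
}

#' @export
print.findex_surfaces <- function(x, ...) {
  cat("findex calibration surfaces (version", x$version, ")\n")
  cat("GD_min (5th percentile of non-null pre-barrier values):\n")
  print(x$gd_min, row.names = FALSE)
  cat("GD_max random-forest fits:\n")
  print(x$fit_stats, row.names = FALSE)
  invisible(x)
}

#' Predict the total-barrier ceiling GD_max
#'
#' Evaluates the four fitted surfaces at a barrier age `T` and mean expected
#' heterozygosity `He`. Queries outside the training domain (`T` in (0,
#' t_max], `He` in `[0, 0.93]`) are clamped to the domain edge with a warning;
#' predictions are floored at the corresponding `GD_min` so the calibration
#' envelope never inverts.
#'
#' @param surfaces a `findex_surfaces` object.
#' @param T barrier age in generations (may be fractional).
#' @param He mean expected heterozygosity of the two populations.
#' @return data.frame with columns `metric`, `mu`, `gd_min`, `gd_max`,
#'   `clamped_domain`.
#' @export
predict_gd_max <- function(surfaces, T, He) {
  stopifnot(inherits(surfaces, "findex_surfaces"))
  if (!length(surfaces$models)) stop("surfaces carry no fitted models")
  if (T <= 0) stop("barrier age T must be > 0")
  clamped <- FALSE
  t_max <- surfaces$t_domain[2]
  if (T > t_max) {
    warning("T = ", T, " beyond training domain; clamped to ", t_max)
    T <- t_max
    clamped <- TRUE
  }
  if (He < surfaces$he_domain[1] || He > surfaces$he_domain[2]) {
    He_cl <- min(max(He, surfaces$he_domain[1]), surfaces$he_domain[2])
    warning("He = ", He, " outside training domain; clamped to ", He_cl)
    He <- He_cl
    clamped <- TRUE
  }
  newdata <- data.frame(T = T, He = He)
  out <- surfaces$gd_min
  out$gd_max <- NA_real_
  for (i in seq_len(nrow(out))) {
    key <- surface_key(out$metric[i], out$mu[i])
    model <- surfaces$models[[key]]
    if (is.null(model)) stop("no fitted surface for ", key)
    pred <- unname(predict(model, newdata))
    out$gd_max[i] <- max(pred, out$gd_min[i])
  }
  out$clamped_domain <- clamped
  out
}

#' Persist / restore a calibration bundle
#'
#' The bundle is saved with R serialization together with its version stamp,
#' training grid and seeds; [load_surfaces()] refuses bundles with a
#' different schema version. A round-trip reproduces predictions bit-exactly.
#'
#' @param surfaces a `findex_surfaces` object.
#' @param path file path for the bundle.
#' @return `path` (save) or the restored `findex_surfaces` object (load).
#' @export
save_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "findex_surfaces"))
  saveRDS(surfaces, path)
  invisible(path)
}

#' @rdname save_surfaces
#' @export
load_surfaces <- function(path) {
  if (!file.exists(path)) stop("surfaces bundle not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupted surfaces bundle: ",
                                           conditionMessage(e)))
  if (!inherits(obj, "findex_surfaces"))
    stop("file is not a findex surfaces bundle")
  if (!identical(obj$version, SURFACES_VERSION))
    stop("surfaces bundle version ", obj$version,
         " incompatible with expected version ", SURFACES_VERSION)
  obj
}

#' Plain-text manifest of a calibration bundle
#'
#' @param surfaces a `findex_surfaces` object.
#' @return character vector of manifest lines (GD_min values, OOB fit
#'   statistics, grid and seed), suitable for `writeLines()`.
#' @export
surfaces_manifest <- function(surfaces) {
  stopifnot(inherits(surfaces, "findex_surfaces"))
  g <- surfaces$grid
  c(sprintf("findex surfaces manifest (version %s)", surfaces$version),
    sprintf("seed: %d", surfaces$seed),
    sprintf("grid: K in {%s}; mu in {%s}; %d replicates; %d sampling times",
            paste(g$K_levels, collapse = ","),
            paste(g$mu_levels, collapse = ","),
            g$n_reps, length(g$sample_times)),
    "gd_min:",
    sprintf("  %s mu=%g: %.6g (n=%d)", surfaces$gd_min$metric,
            surfaces$gd_min$mu, surfaces$gd_min$gd_min,
            surfaces$gd_min$n_records),
    "gd_max fits:",
    sprintf("  %s mu=%g: OOB var explained %.1f%%, OOB MSE %.5f (n=%d)",
            surfaces$fit_stats$metric, surfaces$fit_stats$mu,
            surfaces$fit_stats$oob_var_explained,
            surfaces$fit_stats$oob_mse, surfaces$fit_stats$n_records))
}
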