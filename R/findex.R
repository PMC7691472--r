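#' Fragmentation sub-index for one metric and one mutation rate
#'
#' Rescales an observed differentiation value between the no-barrier floor
#' and the total-barrier ceiling on a log scale:
#' `F = 100 * (log(gd_min) - log(gd_obs)) / (log(gd_min) - log(gd_max))`.
#' Observations at or below `gd_min` (including exact zeros) score 0;
#' observations at or above `gd_max` score 100. Clamping is reported in the
#' `"clamped"` attribute of the result.
#'
#' @param gd_obs observed differentiation value(s), >= 0.
#' @param gd_min no-barrier floor (> 0).
#' @param gd_max total-barrier ceiling (> gd_min).
#' @return numeric vector of sub-indices in `[0, 100]`, with a logical
#'   attribute `clamped` marking entries pinned at 0 or 100.
#' @examples
#' findex_single(0.05, gd_min = 0.001, gd_max = 0.5)  # 62.95
#' @export
findex_single <- function(gd_obs, gd_min, gd_max) {
  if (any(gd_min <= 0)) stop("gd_min must be > 0")
  if (any(gd_max <= gd_min))
    stop("invalid surfaces: gd_max must exceed gd_min")
  if (any(gd_obs < 0, na.rm = TRUE)) stop("gd_obs must be >= 0")
  n <- max(length(gd_obs), length(gd_min), length(gd_max))
  gd_obs <- rep_len(gd_obs, n)
  gd_min <- rep_len(gd_min, n)
  gd_max <- rep_len(gd_max, n)
  f <- 100 * (log(gd_min) - log(gd_obs)) / (log(gd_min) - log(gd_max))
  clamped <- !is.na(gd_obs) & (gd_obs <= gd_min | gd_obs >= gd_max)
  f[!is.na(gd_obs) & gd_obs <= gd_min] <- 0
  f[!is.na(gd_obs) & gd_obs >= gd_max] <- 100
  attr(f, "clamped") <- clamped
  f
}

#' Average the four sub-indices into a final index with a 95% CI
#'
#' Undefined sub-indices are dropped (and counted). The default standard
#' error follows the published rule SE = sd / 4; `se_rule = "conventional"`
#' uses the usual SE = sd / sqrt(n). The 95% confidence half-width is
#' 1.96 * SE.
#'
#' @param indices numeric vector of sub-indices (percent), possibly with
#'   `NA` for undefined metric combinations.
#' @param se_rule `"paper"` (sd / 4) or `"conventional"` (sd / sqrt(n)).
#' @return list with `mean`, `ci95` (half-width; `NA` when fewer than two
#'   valid sub-indices), `se`, `n_valid`, `n_dropped`.
#' @examples
#' findex_mean(c(50, 60, 55, 45))  # mean 52.5, ci95 3.163
#' @export
findex_mean <- function(indices, se_rule = c("paper", "conventional")) {
  se_rule <- match.arg(se_rule)
  valid <- indices[!is.na(indices)]
  n <- length(valid)
  if (n == 0) stop("no valid sub-index to average")
  m <- mean(valid)
  if (n < 2) {
    return(list(mean = m, ci95 = NA_real_, se = NA_real_,
                n_valid = n, n_dropped = length(indices) - n))
  }
  s <- sd(valid)
  se <- if (se_rule == "paper") s / 4 else s / sqrt(n)
  list(mean = m, ci95 = 1.96 * se, se = se,
       n_valid = n, n_dropped = length(indices) - n)
}

#' Overall index across several datasets of the same obstacle
#'
#' When several genotypic datasets (species, replicates) are available for
#' one obstacle, the sub-indices are pooled in an intercept-only linear
#' mixed model with the dataset as a random effect (REML). The overall
#' index is the fixed intercept and the 95% CI half-width is 1.96 times the
#' model standard error of the intercept, which accounts for the
#' non-independence of sub-indices from the same dataset. With a single
#' dataset the function falls back to [findex_mean()].
#'
#' @param indices numeric vector of sub-indices (percent).
#' @param dataset factor/character of the same length identifying the
#'   genotypic dataset each sub-index comes from.
#' @param se_rule passed to [findex_mean()] for the single-dataset fallback.
#' @return list with `estimate`, `ci95`, `se`, `n_datasets`, `singular`
#'   (TRUE when the between-dataset variance degenerated to zero and the
#'   model collapsed to a pooled mean).
#' @export
findex_overall <- function(indices, dataset,
                           se_rule = c("paper", "conventional")) {
  se_rule <- match.arg(se_rule)
  keep <- !is.na(indices)
  indices <- indices[keep]
  dataset <- factor(dataset[keep])
  if (!length(indices)) stop("no valid sub-index")
  n_ds <- nlevels(dataset)
  if (n_ds < 2) {
    fm <- findex_mean(indices, se_rule = se_rule)
    return(list(estimate = fm$mean, ci95 = fm$ci95, se = fm$se,
                n_datasets = n_ds, singular = FALSE))
  }
  d <- data.frame(y = indices, ds = dataset)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | ds), data = d, REML = TRUE)))
  est <- unname(lme4::fixef(fit)[1])
  se <- tryCatch(
    sqrt(as.numeric(suppressWarnings(stats::vcov(fit))[1, 1])),
    error = function(e) NA_real_)
  if (!is.finite(se)) {
    # fully degenerate fit (e.g. zero variance everywhere): fall back to
    # the empirical standard error of the dataset means
    means <- tapply(indices, dataset, mean)
    se <- stats::sd(means) / sqrt(length(means))
    if (!is.finite(se)) se <- 0
  }
  list(estimate = est, ci95 = 1.96 * se, se = se, n_datasets = n_ds,
       singular = lme4::isSingular(fit))
}

#' Compute the fragmentation index for one obstacle
#'
#' End-to-end scoring of one obstacle from genotypes: extracts the upstream
#' and downstream populations, computes their mean expected heterozygosity
#' and the observed Hedrick G''st and Meirmans phi'st, queries the
#' calibration surfaces at the obstacle's age `T`, computes the four
#' sub-indices (two metrics x two calibration mutation rates) and averages
#' them with a 95% CI. A warning is issued for obstacles younger than 10
#' generations, where background noise is not yet separable from a true
#' barrier signal.
#'
#' @param dataset a [genotype_dataset()] containing both populations.
#' @param pop_up,pop_down names of the populations flanking the obstacle.
#' @param T number of generations since barrier creation (fractional values
#'   allowed; passed to the surfaces as-is).
#' @param surfaces a `findex_surfaces` bundle (see [build_surfaces()]), or
#'   `NULL` when `user_gd` supplies the envelope directly.
#' @param user_gd optional data.frame with columns `metric`, `mu`,
#'   `gd_min`, `gd_max` overriding the surfaces (the envelope a user
#'   calibrated elsewhere).
#' @param se_rule passed to [findex_mean()].
#' @return an object of class `findex_result`: list with `pop_up`,
#'   `pop_down`, `T`, `He_mean`, `table` (per metric x mu: `gd_obs`,
#'   `gd_min`, `gd_max`, `index`, `clamped`), `findex`, `ci95`, `n_valid`,
#'   `flags`.
#' @export
compute_for_obstacle <- function(dataset, pop_up, pop_down, T,
                                 surfaces = NULL, user_gd = NULL,
                                 se_rule = c("paper", "conventional")) {
  se_rule <- match.arg(se_rule)
  if (T < 1) stop("barrier age T must be >= 1 generation")
  flags <- character(0)
  if (T < 10) {
    warning("T = ", T, " < 10 generations: the index cannot yet be ",
            "separated from background noise at this age")
    flags <- c(flags, "T_below_10")
  }
  pair <- subset_populations(dataset, c(pop_up, pop_down))
  st <- diff_stats(pair)
  obs <- c(Gpp_st = st$Gpp_st, phip_st = st$phip_st)

  if (!is.null(user_gd)) {
    need <- c("metric", "mu", "gd_min", "gd_max")
    if (!all(need %in% names(user_gd)))
      stop("user_gd must have columns ", paste(need, collapse = ", "))
    env <- user_gd[, need]
    flags <- c(flags, "user_envelope")
  } else {
    if (is.null(surfaces)) stop("either surfaces or user_gd is required")
    env <- withCallingHandlers(
      predict_gd_max(surfaces, T = T, He = st$He_mean),
      warning = function(w) {
        flags <<- c(flags, "domain_clamped")
        invokeRestart("muffleWarning")
      })
  }

  tab <- env[, c("metric", "mu", "gd_min", "gd_max")]
  tab$gd_obs <- unname(obs[tab$metric])
  tab$index <- NA_real_
  tab$clamped <- FALSE
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$gd_obs[i])) next  # undefined metric dropped from the mean
    f <- findex_single(max(0, tab$gd_obs[i]), tab$gd_min[i], tab$gd_max[i])
    tab$index[i] <- as.numeric(f)
    tab$clamped[i] <- attr(f, "clamped")
  }
  if (any(is.na(tab$index))) flags <- c(flags, "undefined_metric_dropped")
  if (any(tab$clamped, na.rm = TRUE)) flags <- c(flags, "index_clamped")
  fm <- findex_mean(tab$index, se_rule = se_rule)
  structure(list(pop_up = pop_up, pop_down = pop_down, T = T,
                 He_mean = st$He_mean, table = tab,
                 findex = fm$mean, ci95 = fm$ci95, n_valid = fm$n_valid,
                 flags = unique(flags)),
            class = "findex_result")
}

#' @export
print.findex_result <- function(x, ...) {
  cat(sprintf("Fragmentation index: %s vs %s (T = %g generations)\n",
              x$pop_up, x$pop_down, x$T))
  cat(sprintf("  He_mean = %.3f\n", x$He_mean))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-8s mu=%-6g GD_obs=%.4g in [%.4g, %.4g] -> %s\n",
                tab$metric[i], tab$mu[i], tab$gd_obs[i], tab$gd_min[i],
                tab$gd_max[i],
                ifelse(is.na(tab$index[i]), "undefined",
                       sprintf("%.2f%%", tab$index[i]))))
  ci <- if (is.na(x$ci95)) "CI unavailable" else sprintf("+/- %.2f", x$ci95)
  cat(sprintf("  F_INDEX = %.2f%% (%s; %d valid sub-indices)\n",
              x$findex, ci, x$n_valid))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
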