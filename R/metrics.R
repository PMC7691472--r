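# Per-locus allele bookkeeping shared by the diversity and differentiation
# estimators. Returns, for one locus, the per-population allele count table
# (alleles x pops) restricted to scored genotypes.
locus_counts <- function(dataset, l) {
  pops <- dataset$pops
  all_states <- sort(unique(unlist(lapply(pops, function(p)
    as.vector(p[, c(2 * l - 1, 2 * l)])))))
  all_states <- all_states[!is.na(all_states)]
  counts <- matrix(0L, nrow = length(all_states), ncol = length(pops),
                   dimnames = list(all_states, names(pops)))
  n_ind <- integer(length(pops))
  ho <- numeric(length(pops))
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    a1 <- p[, 2 * l - 1]
    a2 <- p[, 2 * l]
    ok <- !is.na(a1)
    n_ind[i] <- sum(ok)
    if (n_ind[i]) {
      idx <- match(c(a1[ok], a2[ok]), all_states)
      counts[, i] <- tabulate(idx, nbins = length(all_states))
      ho[i] <- mean(a1[ok] != a2[ok])
    }
  }
  list(counts = counts, n_ind = n_ind, ho = ho)
}

#' Expected heterozygosity (unbiased gene diversity)
#'
#' Per locus and per population, computes the small-sample-corrected gene
#' diversity `He = (2n / (2n - 1)) * (1 - sum(p_a^2))` with `n` the number of
#' scored individuals. Per-population values are averaged over loci, and the
#' summary `He_mean` is the arithmetic mean of the per-population averages.
#' A locus with no scored genotype in a population is dropped from that
#' population's average with a warning.
#'
#' @param dataset a [genotype_dataset()].
#' @return a list with `per_locus` (loci x populations matrix), `per_pop`
#'   (named vector of per-population averages) and `He_mean`.
#' @examples
#' up <- matrix(rep(c(1L, 2L), 10), nrow = 10, byrow = TRUE)
#' he <- expected_heterozygosity(genotype_dataset(list(A = up), "L1"))
#' he$He_mean  # (20/19) * (1 - 0.5) = 0.5263
#' @export
expected_heterozygosity <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  L <- length(dataset$loci)
  k <- length(dataset$pops)
  per_locus <- matrix(NA_real_, nrow = L, ncol = k,
                      dimnames = list(dataset$loci, names(dataset$pops)))
  for (l in seq_len(L)) {
    lc <- locus_counts(dataset, l)
    for (i in seq_len(k)) {
      n <- lc$n_ind[i]
      if (n == 0) next
      p <- lc$counts[, i] / (2 * n)
      per_locus[l, i] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    }
  }
  if (anyNA(per_locus))
    warning("locus/population combinations without data dropped from He")
  per_pop <- colMeans(per_locus, na.rm = TRUE)
  list(per_locus = per_locus, per_pop = per_pop,
       He_mean = mean(per_pop))
}

#' Hedrick's standardized G''st between two populations
#'
#' Multilocus Hedrick G''st with the Nei & Chesser bias-corrected gene
#' diversities. Per locus, with harmonic-mean sample size `nh` over the two
#' populations and mean observed heterozygosity `Ho`:
#' `Hs = nh/(nh-1) * (1 - mean_i sum_a p_ia^2 - Ho/(2*nh))` and
#' `Ht = 1 - sum_a pbar_a^2 + Hs/(nh*k) - Ho/(2*nh*k)` with `k = 2`
#' populations. Diversities are averaged over loci before forming
#' `G''st = k*(Ht - Hs) / ((k*Ht - Hs) * (1 - Hs))`; negative values are
#' clamped to 0.
#'
#' @param dataset a [genotype_dataset()] with exactly two populations.
#' @return a single value in `[0, 1]`, or `NA` when the statistic is
#'   undefined (`Hs = 1`, or no polymorphism at all).
#' @export
hedrick_gpp_st <- function(dataset) {
  nc <- nei_chesser_diversities(dataset)
  if (is.na(nc$Hs) || is.na(nc$Ht)) return(NA_real_)
  if (nc$Hs >= 1) return(NA_real_)  # degenerate denominator
  k <- 2
  num <- k * (nc$Ht - nc$Hs)
  den <- (k * nc$Ht - nc$Hs) * (1 - nc$Hs)
  if (den == 0) {
    # no diversity anywhere: identical monomorphic populations
    return(0)
  }
  max(0, num / den)
}

# Nei & Chesser (1983) bias-corrected multilocus diversities for k
# populations; loci for which a population has no data are dropped.
nei_chesser_diversities <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  k <- length(dataset$pops)
  if (k != 2) stop("pairwise statistic: expected exactly 2 populations")
  L <- length(dataset$loci)
  hs <- ht <- numeric(0)
  dropped <- 0
  for (l in seq_len(L)) {
    lc <- locus_counts(dataset, l)
    if (any(lc$n_ind < 2)) { dropped <- dropped + 1; next }
    nh <- k / sum(1 / lc$n_ind)
    freq <- sweep(lc$counts, 2, 2 * lc$n_ind, "/")
    ho <- mean(lc$ho)
    hs_raw <- 1 - mean(colSums(freq^2))
    hs_l <- (nh / (nh - 1)) * (hs_raw - ho / (2 * nh))
    pbar <- rowMeans(freq)
    ht_l <- 1 - sum(pbar^2) + hs_l / (nh * k) - ho / (2 * nh * k)
    hs <- c(hs, hs_l)
    ht <- c(ht, ht_l)
  }
  if (dropped)
    warning(dropped, " locus/loci without >=2 scored individuals in a ",
            "population dropped from differentiation estimates")
  if (!length(hs)) return(list(Hs = NA_real_, Ht = NA_real_))
  list(Hs = mean(hs), Ht = mean(ht))
}

# Two-level AMOVA variance components for one locus on allele identity
# distance (d = 0 same state, 1 otherwise), computed from allele copy counts.
# Returns c(sigma_among, sigma_within).
amova_components <- function(counts) {
  Np <- colSums(counts)
  keep <- Np > 0
  counts <- counts[, keep, drop = FALSE]
  Np <- Np[keep]
  k <- length(Np)
  N <- sum(Np)
  if (k < 2 || N <= k) return(c(NA_real_, NA_real_))
  Ca <- rowSums(counts)
  ss_total <- (N^2 - sum(Ca^2)) / (2 * N)
  ss_within <- sum((Np^2 - colSums(counts^2)) / (2 * Np))
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (k - 1)
  ms_within <- ss_within / (N - k)
  n0 <- (N - sum(Np^2) / N) / (k - 1)
  c(among = (ms_among - ms_within) / n0, within = ms_within)
}

#' Meirmans' standardized phi'st between two populations
#'
#' Two-level AMOVA (among / within populations) on all scored allele copies
#' with the identity distance (0 if two copies carry the same allelic state,
#' 1 otherwise). Variance components are summed over loci before forming
#' `phi_st`. The maximum `phi_st_max` is obtained by recoding alleles so
#' that no state is shared between the two populations while preserving each
#' population's allele-frequency spectrum, and `phi'st = phi_st /
#' phi_st_max`. Negative values are clamped to 0.
#'
#' @param dataset a [genotype_dataset()] with exactly two populations.
#' @return a single value in `[0, 1]`, or `NA` when undefined (no variance
#'   at all, or `phi_st_max <= 0`).
#' @export
meirmans_phi_prime_st <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (length(dataset$pops) != 2)
    stop("pairwise statistic: expected exactly 2 populations")
  L <- length(dataset$loci)
  comp <- matrix(0, nrow = 0, ncol = 2)
  comp_max <- matrix(0, nrow = 0, ncol = 2)
  for (l in seq_len(L)) {
    lc <- locus_counts(dataset, l)
    if (any(lc$n_ind == 0)) next
    cc <- amova_components(lc$counts)
    if (anyNA(cc)) next
    # recode: stack the two populations' alleles on disjoint state sets
    priv <- rbind(cbind(lc$counts[, 1], 0L), cbind(0L, lc$counts[, 2]))
    cc_max <- amova_components(priv)
    comp <- rbind(comp, cc)
    comp_max <- rbind(comp_max, cc_max)
  }
  if (!nrow(comp)) return(NA_real_)
  tot <- colSums(comp)
  tot_max <- colSums(comp_max)
  denom <- sum(tot)
  denom_max <- sum(tot_max)
  if (denom <= 0 && denom_max <= 0) return(NA_real_)
  phi <- if (denom > 0) tot[1] / denom else 0
  phi_max <- if (denom_max > 0) tot_max[1] / denom_max else NA_real_
  if (is.na(phi_max) || phi_max <= 0) return(NA_real_)
  max(0, phi / phi_max)
}

#' All differentiation summaries for a pair of populations
#'
#' Convenience wrapper computing, in one pass, mean expected heterozygosity
#' ([expected_heterozygosity()]), Hedrick's G''st ([hedrick_gpp_st()]) and
#' Meirmans' phi'st ([meirmans_phi_prime_st()]).
#'
#' @param dataset a [genotype_dataset()] with exactly two populations.
#' @return a list with `He_mean`, `Gpp_st`, `phip_st`, `Hs`, `Ht` and
#'   `n_pops`.
#' @export
diff_stats <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (length(dataset$pops) != 2)
    stop("diff_stats expects exactly 2 populations")
  L <- length(dataset$loci)
  he_locus <- matrix(NA_real_, L, 2)
  hs <- ht <- numeric(0)
  comp <- comp_max <- matrix(0, nrow = 0, ncol = 2)
  for (l in seq_len(L)) {
    lc <- locus_counts(dataset, l)
    for (i in 1:2) {
      n <- lc$n_ind[i]
      if (n == 0) next
      p <- lc$counts[, i] / (2 * n)
      he_locus[l, i] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    }
    if (all(lc$n_ind >= 2)) {
      nh <- 2 / sum(1 / lc$n_ind)
      freq <- sweep(lc$counts, 2, 2 * lc$n_ind, "/")
      ho <- mean(lc$ho)
      hs_l <- (nh / (nh - 1)) * (1 - mean(colSums(freq^2)) - ho / (2 * nh))
      hs <- c(hs, hs_l)
      ht <- c(ht, 1 - sum(rowMeans(freq)^2) + hs_l / (2 * nh) -
                ho / (4 * nh))
    }
    if (all(lc$n_ind > 0)) {
      cc <- amova_components(lc$counts)
      if (!anyNA(cc)) {
        priv <- rbind(cbind(lc$counts[, 1], 0L), cbind(0L, lc$counts[, 2]))
        comp <- rbind(comp, cc)
        comp_max <- rbind(comp_max, amova_components(priv))
      }
    }
  }
  # Hedrick's G''st from the accumulated multilocus diversities
  gpp <- NA_real_
  if (length(hs)) {
    Hs <- mean(hs)
    Ht <- mean(ht)
    if (Hs < 1) {
      den <- (2 * Ht - Hs) * (1 - Hs)
      gpp <- if (den == 0) 0 else max(0, 2 * (Ht - Hs) / den)
    }
  }
  # phi'st from summed variance components
  phip <- NA_real_
  if (nrow(comp)) {
    tot <- colSums(comp)
    tot_max <- colSums(comp_max)
    if (sum(tot) > 0 || sum(tot_max) > 0) {
      phi <- if (sum(tot) > 0) tot[1] / sum(tot) else 0
      phi_max <- if (sum(tot_max) > 0) tot_max[1] / sum(tot_max) else NA_real_
      if (!is.na(phi_max) && phi_max > 0) phip <- max(0, phi / phi_max)
    }
  }
  per_pop <- colMeans(he_locus, na.rm = TRUE)
  list(He_mean = mean(per_pop), Gpp_st = gpp, phip_st = unname(phip),
       Hs = if (length(hs)) mean(hs) else NA_real_,
       Ht = if (length(ht)) mean(ht) else NA_real_, n_pops = 2L)
}
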