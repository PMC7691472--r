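# Independent first-principles oracles for the differentiation estimators.
# Deliberately written with explicit loops and no shared code with the
# package internals.

# Hedrick's G''st from raw genotype matrices (list of 2 matrices, n x 2L).
oracle_gpp_st <- function(pops) {
  L <- ncol(pops[[1]]) / 2
  hs_list <- ht_list <- c()
  for (l in seq_len(L)) {
    copies <- list()
    ho <- n <- numeric(2)
    for (p in 1:2) {
      mat <- pops[[p]]
      a1 <- mat[, 2 * l - 1]
      a2 <- mat[, 2 * l]
      ok <- which(!is.na(a1) & !is.na(a2))
      n[p] <- length(ok)
      copies[[p]] <- c(a1[ok], a2[ok])
      ho[p] <- if (n[p]) sum(a1[ok] != a2[ok]) / n[p] else NA
    }
    if (any(n < 2)) next
    states <- sort(unique(c(copies[[1]], copies[[2]])))
    freq <- matrix(0, length(states), 2)
    for (p in 1:2) for (s in seq_along(states))
      freq[s, p] <- sum(copies[[p]] == states[s]) / length(copies[[p]])
    nh <- 2 / (1 / n[1] + 1 / n[2])
    ho_bar <- (ho[1] + ho[2]) / 2
    hs_raw <- 1 - (sum(freq[, 1]^2) + sum(freq[, 2]^2)) / 2
    hs <- (nh / (nh - 1)) * (hs_raw - ho_bar / (2 * nh))
    pbar <- (freq[, 1] + freq[, 2]) / 2
    ht <- 1 - sum(pbar^2) + hs / (2 * nh) - ho_bar / (4 * nh)
    hs_list <- c(hs_list, hs)
    ht_list <- c(ht_list, ht)
  }
  if (!length(hs_list)) return(NA_real_)
  Hs <- mean(hs_list)
  Ht <- mean(ht_list)
  if (Hs >= 1) return(NA_real_)
  den <- (2 * Ht - Hs) * (1 - Hs)
  if (den == 0) return(0)
  max(0, 2 * (Ht - Hs) / den)
}

# AMOVA sums of squares by explicit double loops over allele copies.
oracle_amova_ss <- function(copies) {
  # copies: list of 2 integer vectors (allele states of each population)
  all <- c(copies[[1]], copies[[2]])
  N <- length(all)
  ss_tot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    ss_tot <- ss_tot + (all[i] != all[j])
  ss_tot <- ss_tot / N
  ss_w <- 0
  for (p in 1:2) {
    v <- copies[[p]]
    np <- length(v)
    s <- 0
    if (np > 1)
      for (i in seq_len(np - 1)) for (j in (i + 1):np)
        s <- s + (v[i] != v[j])
    ss_w <- ss_w + s / np
  }
  ss_a <- ss_tot - ss_w
  ms_a <- ss_a / 1
  ms_w <- ss_w / (N - 2)
  n1 <- length(copies[[1]]); n2 <- length(copies[[2]])
  n0 <- (N - (n1^2 + n2^2) / N) / 1
  c(among = (ms_a - ms_w) / n0, within = ms_w)
}

oracle_phip_st <- function(pops) {
  L <- ncol(pops[[1]]) / 2
  comp <- comp_max <- c(0, 0)
  any_locus <- FALSE
  for (l in seq_len(L)) {
    copies <- list()
    for (p in 1:2) {
      mat <- pops[[p]]
      a1 <- mat[, 2 * l - 1]; a2 <- mat[, 2 * l]
      ok <- which(!is.na(a1) & !is.na(a2))
      copies[[p]] <- c(a1[ok], a2[ok])
    }
    if (!length(copies[[1]]) || !length(copies[[2]])) next
    if (length(copies[[1]]) + length(copies[[2]]) <= 2) next
    any_locus <- TRUE
    comp <- comp + oracle_amova_ss(copies)
    # recode population 2 onto a private state set
    recoded <- list(copies[[1]], copies[[2]] + 1000L)
    comp_max <- comp_max + oracle_amova_ss(recoded)
  }
  if (!any_locus) return(NA_real_)
  denom <- sum(comp); denom_max <- sum(comp_max)
  if (denom <= 0 && denom_max <= 0) return(NA_real_)
  phi <- if (denom > 0) comp[1] / denom else 0
  phi_max <- if (denom_max > 0) comp_max[1] / denom_max else NA
  if (is.na(phi_max) || phi_max <= 0) return(NA_real_)
  max(0, phi / phi_max)
}

# random small 2-population dataset (optionally with missing genotypes)
random_toy_dataset <- function(seed, max_loci = 3, max_ind = 12,
                               n_alleles = 4, p_missing = 0.1) {
  set.seed(seed)
  L <- sample(1:max_loci, 1)
  pops <- list()
  for (p in 1:2) {
    n <- sample(3:max_ind, 1)
    mat <- matrix(sample.int(n_alleles, n * 2 * L, replace = TRUE),
                  nrow = n)
    for (l in 1:L) {
      miss <- runif(n) < p_missing
      mat[miss, c(2 * l - 1, 2 * l)] <- NA_integer_
    }
    pops[[p]] <- mat
  }
  names(pops) <- c("A", "B")
  genotype_dataset(pops, sprintf("L%d", 1:L))
}

# closed-form REML for a balanced one-way random-intercept design
oracle_balanced_reml <- function(y, group) {
  group <- factor(group)
  a <- nlevels(group)
  n <- length(y) / a
  means <- tapply(y, group, mean)
  msb <- n * var(as.numeric(means))
  # Var(grand mean) = MSB / (a * n) when sigma_a^2 >= 0
  list(intercept = mean(y), se = sqrt(msb / (a * n)))
}
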