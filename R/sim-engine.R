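#' Define a two-deme forward-simulation scenario
#'
#' A scenario describes one forward-time run of two adjacent demes of constant
#' carrying capacity `K` exchanging migrants at rate `m_before` up to (and
#' including) generation `t_barrier`, and at rate `m_after` afterwards, with
#' diploid genotypes at `n_loci` unlinked microsatellite loci mutating under a
#' bounded stepwise model with `n_alleles` allelic states.
#'
#' The per-generation cycle is migration, then Wright-Fisher reproduction
#' (each of the K offspring of a deme draws two parents uniformly with
#' replacement among the deme's post-migration residents, selfing allowed, and
#' one random allele per locus from each parent), then mutation (each
#' transmitted allele copy mutates with probability `mu[locus]`, moving one
#' state up or down with equal probability and reflecting at states `1` and
#' `n_alleles`).
#'
#' @param K carrying capacity of each deme (diploid individuals, >= 2).
#' @param n_loci number of microsatellite loci.
#' @param n_alleles number of allelic states per locus.
#' @param mu per-locus per-gamete mutation probability; a scalar applied to
#'   all loci or a vector of length `n_loci`.
#' @param m_before migration probability per individual per generation before
#'   barrier creation (0 to 0.5; 0.5 means near-panmixia of the two demes).
#' @param m_after migration probability after barrier creation.
#' @param t_barrier last generation at which `m_before` applies.
#' @param t_end total number of generations simulated.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return an object of class `sim_scenario`.
#' @examples
#' sc <- sim_scenario(K = 100, seed = 1)
#' sc$K
#' @export
sim_scenario <- function(K = 100, n_loci = 15, n_alleles = 20, mu = 5e-4,
                         m_before = 0.5, m_after = 0, t_barrier = 400,
                         t_end = 1000, seed = NULL) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid scenario field '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(K) && length(K) == 1 && K >= 2 && K == round(K),
      "K", "must be a single integer >= 2")
  chk(is.numeric(n_loci) && n_loci >= 1, "n_loci", "must be >= 1")
  chk(is.numeric(n_alleles) && n_alleles >= 2, "n_alleles", "must be >= 2")
  if (length(mu) == 1) mu <- rep(mu, n_loci)
  chk(length(mu) == n_loci, "mu", "must be scalar or length n_loci")
  chk(all(mu >= 0 & mu < 1), "mu", "must satisfy 0 <= mu < 1 per locus")
  chk(m_before >= 0 && m_before <= 0.5, "m_before", "must be in [0, 0.5]")
  chk(m_after >= 0 && m_after <= 0.5, "m_after", "must be in [0, 0.5]")
  chk(t_barrier <= t_end, "t_barrier", "must be <= t_end")
  chk(t_end >= 1, "t_end", "must be >= 1")
  structure(list(K = as.integer(K), n_loci = as.integer(n_loci),
                 n_alleles = as.integer(n_alleles), mu = as.numeric(mu),
                 m_before = m_before, m_after = m_after,
                 t_barrier = as.integer(t_barrier), t_end = as.integer(t_end),
                 seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Two-deme forward simulation scenario\n")
  cat(sprintf("  K = %d, %d loci x %d allelic states\n",
              x$K, x$n_loci, x$n_alleles))
  cat(sprintf("  mu in [%g, %g]\n", min(x$mu), max(x$mu)))
  cat(sprintf("  m = %g up to generation %d, then %g until %d\n",
              x$m_before, x$t_barrier, x$m_after, x$t_end))
  invisible(x)
}

#' Initialize the two demes of a scenario
#'
#' Every allele copy of every individual is drawn independently and uniformly
#' from the `n_alleles` allelic states, mimicking maximal standing variation
#' at the start of a run.
#'
#' @param scenario a [sim_scenario()].
#' @return a list of two integer matrices (one per deme), each of dimension
#'   `K x (2 * n_loci)`; locus `l` occupies columns `2l - 1` and `2l`.
#' @export
init_populations <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  list(cpp_init_pop(scenario$K, scenario$n_loci, scenario$n_alleles),
       cpp_init_pop(scenario$K, scenario$n_loci, scenario$n_alleles))
}

#' Advance the two demes by one generation
#'
#' Applies one cycle of migration, reproduction and mutation (see
#' [sim_scenario()] for the cycle definition). The migration rate is
#' `m_before` when `t <= t_barrier` and `m_after` afterwards.
#'
#' @param states list of two deme matrices as returned by
#'   [init_populations()].
#' @param scenario a [sim_scenario()].
#' @param t the generation index being produced (1-based).
#' @return the updated list of two deme matrices.
#' @export
step_generation <- function(states, scenario, t) {
  stopifnot(inherits(scenario, "sim_scenario"), t >= 1, t <= scenario$t_end)
  m <- if (t <= scenario$t_barrier) scenario$m_before else scenario$m_after
  cpp_step_generation(states[[1]], states[[2]], m, scenario$mu,
                      scenario$n_alleles)
}

#' Run a scenario and sample genotypes along the way
#'
#' Runs the full forward simulation and records, at each requested generation,
#' a subsample of `n_sample` diploid individuals per deme representing the
#' post-dispersal census at each site: every sampled individual attributed to
#' a deme is, with probability equal to the migration rate in effect at that
#' generation, an immigrant drawn from the other deme (all draws without
#' replacement within a source). Under a total barrier this is a plain
#' without-replacement subsample. Sampling is non-destructive and uses a
#' private random stream keyed per sampling generation, so the evolutionary
#' trajectory and any individual sample are identical whatever
#' `sample_times` is.
#'
#' @param scenario a [sim_scenario()].
#' @param sample_times generations at which to sample (subset of
#'   `1..t_end`); may be empty.
#' @param n_sample diploid individuals sampled per deme (<= K).
#' @param pop_names names given to the two demes in the returned datasets.
#' @return a list with one element per sampling time, each a list with
#'   elements `t` (generation), `T` (barrier age `t - t_barrier`) and
#'   `dataset` (a [genotype_dataset()] with the two sampled demes).
#' @examples
#' sc <- sim_scenario(K = 50, n_loci = 3, t_barrier = 10, t_end = 20, seed = 1)
#' samp <- run_scenario(sc, sample_times = 20, n_sample = 10)
#' samp[[1]]$T
#' @export
run_scenario <- function(scenario, sample_times, n_sample = 30,
                         pop_names = c("UP", "DOWN")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sample_times <- as.integer(sample_times)
  if (length(sample_times) &&
      (min(sample_times) < 1 || max(sample_times) > scenario$t_end))
    stop("sample_times must lie within [1, t_end]")
  if (n_sample > scenario$K)
    stop("n_sample (", n_sample, ") exceeds carrying capacity K (",
         scenario$K, ")")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  sample_seed <- sample.int(.Machine$integer.max, 1)
  raw <- cpp_run_scenario(scenario$K, scenario$n_loci, scenario$n_alleles,
                          scenario$mu, scenario$m_before, scenario$m_after,
                          scenario$t_barrier, scenario$t_end,
                          sample_times, as.integer(n_sample),
                          as.double(sample_seed))
  loci <- sprintf("Locus%02d", seq_len(scenario$n_loci))
  lapply(raw, function(s) {
    pops <- list(s$deme1, s$deme2)
    names(pops) <- pop_names
    list(t = s$t, T = s$t - scenario$t_barrier,
         dataset = genotype_dataset(pops, loci))
  })
}

#' Draw heterogeneous per-locus mutation rates
#'
#' Draws `n_loci` stepwise-mutation rates from a lognormal distribution
#' truncated to `[low, high]` whose (truncated) arithmetic mean equals
#' `mean`, emulating the natural rate variability of microsatellite panels.
#' The log-scale standard deviation is set so the allowed range spans four
#' standard deviations, and the log-scale location is solved numerically so
#' the truncated mean matches.
#'
#' @param n_loci number of rates to draw.
#' @param low,high truncation bounds (per-gamete mutation probabilities).
#' @param mean target arithmetic mean of the truncated distribution.
#' @param seed optional integer seed.
#' @return numeric vector of length `n_loci`, all values in `[low, high]`.
#' @examples
#' draw_locus_mutation_rates(15, seed = 1)
#' @export
draw_locus_mutation_rates <- function(n_loci, low = 5e-5, high = 5e-3,
                                      mean = 5e-4, seed = NULL) {
  if (!(low < mean && mean < high))
    stop("infeasible mutation-rate specification: need low < mean < high")
  if (!is.null(seed)) set.seed(seed)
  sdlog <- (log(high) - log(low)) / 4
  trunc_mean <- function(meanlog) {
    a <- (log(low) - meanlog) / sdlog
    b <- (log(high) - meanlog) / sdlog
    exp(meanlog + sdlog^2 / 2) *
      (pnorm(b - sdlog) - pnorm(a - sdlog)) / (pnorm(b) - pnorm(a))
  }
  meanlog <- uniroot(function(ml) trunc_mean(ml) - mean,
                     lower = log(low), upper = log(high), tol = 1e-12)$root
  out <- numeric(0)
  while (length(out) < n_loci) {
    cand <- rlnorm(2 * (n_loci - length(out)) + 8, meanlog, sdlog)
    out <- c(out, cand[cand >= low & cand <= high])
  }
  out[seq_len(n_loci)]
}
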