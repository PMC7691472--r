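---
title: "Methods: a standardized genetic index of river fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a standardized genetic index of river fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Weirs and dams fragment river networks. An indirect way to score the
barrier effect of one obstacle is to genotype the fish populations
immediately upstream and downstream of it and measure their neutral
genetic differentiation: a barrier to gene flow lets drift decouple the
two allele-frequency pools. Raw differentiation is, however, not
comparable across obstacles, because it grows with the age of the obstacle
(in generations, T) and shrinks with effective population size Ne: an old
weir across a small headwater population can show more differentiation
than a recent impassable dam across a large river population.

The fragmentation index implemented here removes both confounders by
rescaling the observed differentiation GD_obs between two
simulation-calibrated anchors:

* **GD_min** — the background differentiation expected with *no* barrier
  (crossing rate m = 0.5, i.e. the two sites behave as one population),
  driven only by drift, mutation and finite sampling;
* **GD_max(T, He)** — the differentiation expected if the obstacle were a
  *total* barrier (m = 0) of age T separating populations whose mean
  expected heterozygosity is He (the Ne proxy).

For each differentiation metric the index is

F = 100 * (ln GD_min - ln GD_obs) / (ln GD_min - ln GD_max),

clamped to [0, 100]: 0% means "indistinguishable from no barrier", 100%
means "indistinguishable from a total barrier". The log scale matches the
roughly geometric growth of differentiation with isolation time.

Four sub-indices are computed per obstacle — two metrics (Hedrick's G″st
and Meirmans' φ′st) crossed with two calibration mutation rates (5e-5 and
5e-4 per gamete per generation, bracketing microsatellite reality) — and
averaged. The published standard-error rule for that average, SE = sd / 4,
is reproduced verbatim (note that the conventional standard error of four
values would be sd / sqrt(4) = sd / 2; `se_rule = "conventional"` switches
to it, the default keeps the published rule for reproducibility). When
several genotypic datasets (e.g. sympatric species) cover the same
obstacle, an intercept-only linear mixed model with dataset as random
effect (REML, via lme4) pools the sub-indices; the overall index is the
fixed intercept and its 95% CI is 1.96 times the model SE.

## The simulator

`sim_scenario()` / `run_scenario()` implement a two-deme individual-based
forward simulator that generates all calibration and validation data:

* two demes of constant carrying capacity K (30–2000), nonoverlapping
  generations;
* per-generation cycle: **migration** (each individual relocates
  independently with probability m), then **Wright–Fisher reproduction**
  (each deme produces exactly K diploid offspring; each offspring draws
  two parents uniformly with replacement among the deme's post-migration
  residents — selfing allowed, no sexes — and one random allele per locus
  from each parent, free recombination), then **stepwise mutation** (each
  transmitted allele copy mutates with probability mu, moving ±1 state
  with equal probability and reflecting at the bounds of the 20-state
  space);
* 15 microsatellite-like loci, 20 allelic states, initialized uniformly at
  random (maximal standing variation);
* migration m = 0.5 for the first 400 generations (burn-in; the two demes
  behave as one population), then m = m_after for 600 more generations
  (barrier of age T = t - 400).

The inner loop is compiled (Rcpp) and consumes R's RNG, so `set.seed()`
makes entire runs bit-reproducible. A generation at K = 1000 costs ~0.2 ms
per simulated generation on one core, which is what makes the full
93-level calibration ladder affordable on a laptop.

**Observation model.** Sampled genotypes represent the *post-dispersal*
census at each site: at a sampling generation the current cohort is
partitioned by a realized dispersal event (each individual relocates with
probability m) and up to 30 individuals are drawn without replacement from
each realized patch. This mirrors the breed-then-disperse life cycle of
standard forward simulators and, more importantly, what an empiricist
nets next to an obstacle: residents plus the crossers of that generation.
The choice is consequential at high m: sampling newborn cohorts instead
would retain the ~1/(2K) single-generation drift differentiation between
demes even under full mixing, which inflates the index for young, highly
permeable obstacles and contradicts the behaviour the index is designed
to have (near 0 under full connectivity). Under a total barrier (m = 0)
the two definitions coincide. Sampling uses a private random stream keyed
by generation, so it never perturbs the trajectory and a sample at
generation t is identical whatever other generations are sampled.

## Estimators

`expected_heterozygosity()` uses the unbiased gene diversity
(2n/(2n-1)) (1 - sum p²) per locus and population, averaged over loci,
then over the two populations.

`hedrick_gpp_st()` implements the bias-corrected Nei–Chesser gene
diversities (harmonic-mean sample size, observed-heterozygosity
correction), averages Hs and Ht over loci, and standardizes:
G″st = k (Ht - Hs) / ((k Ht - Hs)(1 - Hs)) with k = 2.

`meirmans_phi_prime_st()` runs a two-level AMOVA on all scored allele
copies with the identity distance (0 if same allelic state, 1 otherwise),
sums variance components over loci, and divides φst by its maximum
φst_max, obtained by recoding alleles so that no state is shared between
populations while preserving each population's frequency spectrum. The
identity distance (not a squared-step microsatellite distance) is required
for that recoding standardization to be meaningful.

Negative estimates of either metric are clamped to 0. Both estimators are
verified in the test suite against independent brute-force
implementations (explicit double loops over allele copies) to 1e-10 on
randomized small datasets, and on limiting cases (reciprocally fixed
populations → 1; identical populations → 0).

## Calibration surfaces

`build_surfaces()` simulates a training grid and fits the envelope:

* **GD_min**: 5th percentile (linear-interpolation quantile) of the
  *non-zero* metric values among pre-barrier records (T ≤ 0, sustained
  m = 0.5), per metric and mutation rate. Zeros are excluded because
  roughly half of the background estimates clamp to 0; the floor
  characterizes the nonzero background noise.
* **GD_max**: a random-forest regression (randomForest, 200 trees,
  per-tree bootstrap samples of 500 records) of the post-barrier (T > 0)
  metric value on T and He, per metric and mutation rate. Out-of-bag
  explained variance and MSE are stored with every fit; predictions are
  floored at the corresponding GD_min and queries outside the training
  domain (T in (0, 600], He in [0, 0.93]) are clamped to the edge with a
  warning.

**The K ladder.** The default (`training_grid_reduced()`) simulates 93
carrying capacities spaced linearly from 30 to 2000 (step 21.4) with two
replicates each, sampling 30 genotypes every 10 generations from t = 300
to 1000 (71 times, 11 of them pre-barrier). Linear spacing is a
substantive choice, not a convenience: it places only ~5% of training
records below K ≈ 130, where low-mutation small populations fix during
burn-in and the metrics become bimodal (0 if both demes fixed the same
allele, ~1 otherwise) — irreducible noise that no (T, He) model can
explain. With linear weighting the four forests reach ~89–92% out-of-bag
explained variance and OOB MSE ≤ 0.6%; a geometric ladder densified at
small K caps the low-mutation fits near 55% regardless of sample size.
`training_grid_paper()` is the same ladder with ten replicates (132,060
sampled datasets); the reduced default is a pure replication reduction
that preserves the K-weighting and runs in ~3 minutes.

## Validation harness

`run_validation()` rebuilds the index's operating characteristics from
scratch: scenarios with per-locus mutation rates drawn from a lognormal
truncated to [5e-5, 5e-3] with arithmetic mean 5e-4 (the log-scale SD is
set so the allowed range spans four SDs and the location is solved
numerically for the truncated mean), K in {50, 100, 250, 500, 1000},
post-barrier crossing rates m from 0 to 0.5, samples at T in
{5, 10, 15, 20, 25, 50, 100, 300}, and replicate aggregation through the
intercept-only mixed model. The acceptance checks use 20 replicates per
cell (the full design's replication) but only the crossing-rate levels
the benchmarks require — with the compiled simulator the full validation
set for those levels runs in about two minutes.

Expected behaviour, reproduced by the test suite: total barriers (m = 0)
older than ~10 generations always have CIs reaching at least 90%;
high-connectivity obstacles (m > 0.2) always have CIs reaching at most
20%; at intermediate permeability (m = 0.05) the index declines mildly
with T (~65% at T = 15 to ~46% at T = 300) and with K (~70% at K = 50 to
~43% at K = 1000) — a known, documented bias of the method at low
crossing rates, not a defect of this implementation.

`sensitivity_T()` re-scores existing records under multiplicative errors
in T (a user mis-estimating generation time); `sensitivity_markers()`
re-scores with subsampled locus panels.

## Numerical and design choices

* Event order within a generation (migration → reproduction → mutation)
  and the post-dispersal observation model are documented above; the
  order marginally affects the drift–migration interplay only at the
  barrier-onset boundary.
* Generation t uses the pre-barrier migration rate while t ≤ 400, so the
  eleven samples at t = 300…400 are all genuinely pre-barrier.
* The degenerate-denominator cases (Hs = 1 for G″st, zero total variance
  for φ′st) return NA; such sub-indices are dropped from the average and
  flagged (`undefined_metric_dropped`).
* GD_obs at or below GD_min (including exact zeros from negative
  clamping) maps to index 0; at or above GD_max to 100; both flagged.
* Fractional barrier ages (e.g. 15.33 generations from age-in-years /
  generation-time) are passed to the surfaces as-is.
* Mixed-model fits that degenerate (zero variance everywhere) fall back
  to the empirical SE of dataset means and are flagged `singular`.
* Surfaces persist via R serialization with a schema version stamp;
  loading a bundle with a different version fails loudly. Round-trips
  reproduce predictions bit-exactly.

## What the generator does and does not emulate

The simulator reproduces the features the calibration depends on: drift
at realistic riverine population sizes, bounded stepwise microsatellite
mutation, symmetric dispersal across one obstacle, and 30-individual
sampling noise. It does not model selection, sex structure, overlapping
generations, asymmetric (downstream-biased) gene flow, more than two
demes, spatial river topology, or genotyping error. Passing validation
therefore shows that the *index machinery* behaves as designed under its
own stated model, not that any particular empirical system satisfies that
model; for real obstacles the practitioner must still justify adjacent
sampling, the generation-time estimate behind T, and the absence of
confounding tributaries.

## Known limitations

* Within ~10 generations of barrier creation the index is biased
  downward and is flagged accordingly (`T_below_10`).
* At low but nonzero crossing rates the index declines slowly with T and
  K (see above); comparisons are cleanest between obstacles of broadly
  similar age.
* Calibration is specific to 15-locus, 20-allele microsatellite panels
  sampled at ~30 individuals per side; SNP panels or very different
  designs require retraining the surfaces (`findex_train()`) and possibly
  different metrics.
* The published empirical re-analyses require the original genotype
  files; `findex_run()` can score them when the user supplies genepop
  files and a parameter table, but no empirical result is bundled here.
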