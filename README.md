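# findex

**findex** scores the individual barrier effect of a river obstacle (weir,
dam, culvert) on an absolute 0–100% scale from diploid microsatellite
genotypes of the two populations sampled immediately upstream and
downstream of it. It is aimed at population geneticists and environmental
managers who need barrier effects that are comparable across obstacles of
different ages and across populations (or species) of different effective
sizes — for prioritizing restoration and for evaluating it afterwards.

## The index

Observed neutral differentiation between the two flanking populations
grows with the age of the obstacle (T generations) and shrinks with
effective population size, so raw values are not comparable between
obstacles. The fragmentation index rescales the observed differentiation
GD_obs between two simulation-calibrated anchors on a log scale:

    F = 100 · (ln GD_min − ln GD_obs) / (ln GD_min − ln GD_max(T, He))

* `GD_min` — background differentiation with no barrier (crossing rate
  m = 0.5): the 5th percentile of non-zero differentiation across
  pre-barrier two-deme forward simulations.
* `GD_max(T, He)` — differentiation expected under a *total* barrier
  (m = 0) of age `T` between populations of mean expected heterozygosity
  `He` (a proxy for Ne): a random-forest regression surface trained on
  post-barrier simulations (carrying capacities 30–2000, bounded
  stepwise-mutation microsatellites, 15 loci × 20 alleles).

Two differentiation metrics (Hedrick's G″st, Meirmans' φ′st) × two
calibration mutation rates (5·10⁻⁵, 5·10⁻⁴) give four sub-indices, which
are averaged with a 95% CI; several datasets covering the same obstacle
are pooled with an intercept-only mixed model (dataset as random effect).
0% ≈ no barrier effect, 100% ≈ total barrier; validation places "total
barrier" calls above 90% and "free gene flow" calls below 20%.

## Worked example

Everything below is generated by the package itself (no external data).
Train reduced calibration surfaces (~3 min), simulate a total barrier and
an obstacle with 5% crossing rate, and score both:

```r
library(findex)

surf <- findex_train("surfaces.rds", seed = 101)  # 93 K-levels, 2 replicates

findex_simulate("barrier", K = 250, m_after = 0,    sample_times = 500, seed = 42)
findex_simulate("leaky",   K = 250, m_after = 0.05, sample_times = 500, seed = 43)

ds <- read_genepop("barrier_t500.gen")
compute_for_obstacle(ds, "UP", "DOWN", T = 100, surfaces = surf)
```

```
Fragmentation index: UP vs DOWN (T = 100 generations)
  He_mean = 0.582
  Gpp_st   mu=5e-05  GD_obs=0.36 in [0.0009687, 0.3839] -> 98.92%
  phip_st  mu=5e-05  GD_obs=0.36 in [0.001068, 0.3941] -> 98.47%
  Gpp_st   mu=0.0005 GD_obs=0.36 in [0.0009699, 0.4241] -> 97.30%
  phip_st  mu=0.0005 GD_obs=0.36 in [0.0008769, 0.4264] -> 97.26%
  F_INDEX = 97.99% (+/- 0.41; 4 valid sub-indices)
```

```r
compute_for_obstacle(read_genepop("leaky_t500.gen"), "UP", "DOWN",
                     T = 100, surfaces = surf)
```

```
Fragmentation index: UP vs DOWN (T = 100 generations)
  He_mean = 0.626
  Gpp_st   mu=5e-05  GD_obs=0.01642 in [0.0009687, 0.3708] -> 47.59%
  phip_st  mu=5e-05  GD_obs=0.0171 in [0.001068, 0.3686] -> 47.45%
  Gpp_st   mu=0.0005 GD_obs=0.01642 in [0.0009699, 0.4164] -> 46.67%
  phip_st  mu=0.0005 GD_obs=0.0171 in [0.0008769, 0.4287] -> 47.97%
  F_INDEX = 47.42% (+/- 0.27; 4 valid sub-indices)
```

The simulated total barrier scores ~98% while the obstacle crossed at
rate 0.05 scores ~47% at T = 100 (partial permeability; validation places
low-m obstacles of this age and size in the 40–70% band). GD_obs is the
observed metric value, the bracket is the calibrated [GD_min, GD_max]
envelope at (T, He), and each row's percentage is that sub-index.

For batch use, `findex_run()` takes a genepop file plus a parameter table
(columns `obstacle`, `dataset`, `pop_up`, `pop_down`, `T`, optional
`file`) and writes `findex_results.tsv` / `findex_overall.tsv`; a thin
command-line wrapper lives at `inst/cli/findex.R`
(`Rscript inst/cli/findex.R run --genepop f.gen --params p.tsv
--surfaces s.rds --out results/`).

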