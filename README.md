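# morphoclade

Phylogenetic comparative analysis of 3-D landmark shape data, built for
studies that ask how the shape of a skeletal element — the motivating
case is shark lower jaws — diversifies across habitats, diets, trophic
levels and clades. The package takes raw landmark configurations
(multiple specimens per species), a set of candidate phylogenies and a
species ecology table, and carries them through superimposition,
ordination, phylogenetic signal, phylogenetic MANOVA/MANCOVA,
regime-specific evolutionary rates, disparity, disparity-through-time,
ancestral reconstruction and Bayesian branch-specific rate-shift
inference. A synthetic-data generator reproduces the statistical
structure of such a study so the whole pipeline is testable offline.

## The statistics at the core

* **Partial Procrustes GPA with sliding semilandmarks.** Configurations
  are centered, scaled to unit centroid size
  (CS = sqrt(sum_i ||x_i - x_bar||^2)) and rotated by SVD; curve and
  surface semilandmarks slide along tangents / within tangent planes to
  minimise thin-plate-spline bending energy against the consensus.
* **Kmult** — multivariate phylogenetic signal: the mean-squared
  deviation from the phylogenetic mean in ordinary vs
  phylogenetically whitened space, over its Brownian expectation
  (K = 1 under BM), with permutation p-values.
* **PaCA** — ordination whose axes maximise phylogenetically aligned
  variation (GLS-centered data, eigen-decomposition of Y' C Y).
* **Penalized multivariate phylogenetic GLS** with Pagel's lambda / BM /
  EB / OU covariances, ridge-shrunk trait covariance chosen by LOOCV,
  GIC model ranking, and type-II Wilks' lambda MANOVA with
  Freedman-Lane permutations.
* **Mk models and stochastic character mapping** (pruning likelihood,
  ER/SYM/ARD, AIC; uniformisation bridges for branch histories).
* **Regime-specific BM rates** sigma^2_k from character-mapped trees
  (tip covariance sum_k sigma^2_k C_k), per-landmark rate
  decompositions, and fold-change reporting.
* **Procrustes-variance disparity** with within-group bootstraps and
  Wilcoxon/Bonferroni tests; **disparity-through-time** with a
  BM-simulation envelope and an MDI-style area statistic.
* **Reversible-jump MCMC variable-rates model**: branch-specific rate
  scalars with a geometric prior on shift count, plus a
  regime-partitioned rate posterior that integrates stochastic-map
  uncertainty; rank-normalised R-hat and Geyer ESS diagnostics.

## Worked example

```r
library(morphoclade)

spec <- simulation_spec(n_species = 32, n_specimens = 48)  # deep-sea regime 4x faster
sim  <- simulate_study(spec, seed = 3)

al  <- gpa(sim$specimens, slide = TRUE)      # Procrustes + sliding semilandmarks
sh  <- average_by_species(al)                # 32 species x 300 coordinates
tree <- sim$trees[[1]]

shape_pca(sh$shapes)
#> PCA ordination: 31 axes; axis 1 explains 29.36% of variance

kmult(sh$shapes, tree, n_perm = 999, seed = 1)
#> Kmult = 0.6519, p = 0.001 (999 permutations)

hab <- setNames(sim$ecology$habitat, sim$ecology$species)
fit  <- fit_mk(tree, hab, "ER")              # regime model for habitat
maps <- simmap(tree, hab, fit$Q, n_maps = 10, seed = 2)
rr   <- regime_bm_rates(sh, maps)            # per-regime BM rates
rate_fold_changes(rr)
#>     regime reference fold_change
#> 2 deep-sea   pelagic       2.539
#> 3 deep-sea      reef       3.536
#> 4 deep-sea     shelf       3.109
```

Kmult = 0.65 (p = 0.001) says the species shapes carry strong, though
sub-Brownian, phylogenetic signal — the generator evolves shapes by BM
but adds specimen digitisation noise, which dilutes the signal exactly as
measurement error does in real data. The deep-sea regime's rate is
planted 4x higher, and the fold-change table recovers deep-sea as the
fastest habitat (estimates fluctuate around the planted value at 32
species; the acceptance checks average 20 such replicates at 64
species). The printed numbers above are what the code produces for
seed 3.

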