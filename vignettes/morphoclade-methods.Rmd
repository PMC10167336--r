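---
title: "Phylogenetic comparative morphometrics with morphoclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative morphometrics with morphoclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoclade)
```

## What the package models

morphoclade implements a complete comparative-morphometrics workflow for
3-D landmark data on a phylogeny, of the kind used to ask whether jaw (or
any skeletal element) shape diversification is structured by habitat,
diet, trophic level or clade membership. The stages are:

1. **Superimposition.** Generalized Procrustes analysis (GPA) removes
   translation, scale and rotation. We use *partial* Procrustes
   superimposition: every configuration is scaled to unit centroid size
   (CS = root summed squared landmark deviations from the centroid) and
   rotated by the SVD solution, with reflections disallowed because
   landmarks are biologically homologous. Semilandmarks on curves slide
   along their local tangent and surface semilandmarks within their local
   tangent plane to minimise the thin-plate-spline bending energy of the
   deformation from the consensus; the slid positions are the exact
   minimiser of the quadratic bending-energy form, so energy never
   increases within a pass. Tangents come from central differences of
   polyline neighbours; tangent planes from the two leading principal
   directions of the six nearest consensus neighbours. Three sliding
   passes are interleaved with full re-alignment by default (tolerance
   1e-8, at most 100 alignment iterations). Because no meshes are in
   scope, slid points are *not* re-projected onto a specimen surface;
   mesh-based workflows add that step, and results on heavily curved
   structures will differ accordingly.

2. **Ordination and signal.** PCA of the species-mean aligned
   coordinates; phylogenetically aligned component analysis (PaCA,
   "aligned" flavour: the data are centered on the GLS phylogenetic mean
   and axes come from the eigen-decomposition of the cross-product of the
   data with its projection through the tree covariance, so leading axes
   maximise phylogenetically structured variation; percentages are
   reported against total data variance). Multivariate phylogenetic
   signal uses the Kmult statistic — the ratio of mean squared deviation
   from the phylogenetic mean in ordinary versus phylogenetically
   whitened space, scaled by its Brownian expectation — with significance
   from permuting species across tips ((b + 1)/(n + 1) convention). The
   number of "meaningful" axes is the smallest k whose trailing
   eigenvalues pass a Bartlett-type sequential log-likelihood-ratio test
   of homogeneity at alpha = 0.05.

3. **Phylogenetic linear models.** `mvgls_fit()` fits multivariate
   models with Pagel's lambda, Brownian motion, early-burst (EB) or
   Ornstein-Uhlenbeck tree covariances by penalized likelihood: the trait
   covariance of the whitened residuals is shrunk linearly toward its
   diagonal, the shrinkage weight picked by leave-one-out cross-validated
   likelihood on a 10-point log-spaced grid. Two implementation choices
   matter and are deliberate: (i) the LOOCV score includes the whitening
   Jacobian (p/2 log|C|), without which scores are not comparable across
   lambda; (ii) the held-out fold uses a rank-one Woodbury downdate of
   the residual covariance with coefficients held fixed — an
   approximation that keeps the search O(n p^2) per grid point.
   Model comparison uses GIC = -2 logLik + 2 df with
   df = qp + p + (1 - h) p(p - 1)/2 + (extra covariance parameter), i.e.
   the shrunk off-diagonal block contributes fractionally. MANOVA /
   MANCOVA tables are type II with Wilks' lambda computed in a common
   full-rank basis of the whitened residual space (so n < p is handled),
   an F approximation after Rao, and Freedman-Lane permutation of
   reduced-model residuals for p-values. Continuous ancestral states
   solve the inverse-branch-length-weighted tree Laplacian, which equals
   the GLS/ML reconstruction under BM.

4. **Discrete regimes.** Mk models (ER/SYM/ARD) are fitted by
   L-BFGS-B on log rates from three starts, compared by AIC. The root
   prior defaults to FitzJohn state-conditional weighting. Stochastic
   character maps sample node states from their joint conditional
   distribution and then branch histories by uniformisation bridges;
   every map satisfies the structural invariants (segment durations sum
   to branch lengths, tip states honoured, adjacent segments differ).

5. **Rates and disparity.** Regime-specific Brownian rates maximise the
   profiled likelihood of the species shapes under a tip covariance
   `sum_k sigma2_k C_k`, where `C_k` holds the shared branch length spent
   in regime k. The trait side is handled by rotating the data into its
   principal-axis basis once and profiling per-axis variances; profiling
   a full unconstrained trait covariance jointly with the regime scalars
   makes the likelihood unbounded whenever n is small relative to p, the
   diagonal profile in the fixed rotation is bounded and exact in the
   univariate case. The reported scalar rate per regime is the mean of
   the rate-matrix diagonal across all 3p coordinates; per-landmark rates
   sum each landmark's three coordinate rates, and the decomposition
   identity (landmark rates sum to 3p times the scalar rate) holds
   exactly. Disparity is the Procrustes variance (mean squared deviation
   from the group mean, divisor n), bootstrapped within groups (no
   rarefaction by default; a rarefy-to-minimum-n switch exists because
   "overcoming sample-size differences" can reasonably mean either),
   with pairwise Wilcoxon rank-sum tests on the bootstrap distributions
   and Bonferroni correction. Disparity-through-time evaluates mean
   relative subclade disparity at each internal-node height (singleton
   lineages contribute zero) against a 95% envelope of BM simulations
   rate-matched via the contrast covariance, plus an area-between-curves
   (MDI-style) statistic.

6. **Bayesian rate shifts.** The variable-rates model places
   multiplicative scalars on single branches; the number and placement of
   shifts are sampled by reversible jump with a geometric(0.5) prior on
   the shift count, a uniform prior over branch subsets, and a
   log-uniform prior on scalars in [1e-3, 1e3]. Because scalars are
   proposed from their prior and placements uniformly, the acceptance
   ratio reduces to the likelihood ratio times the count-prior ratio.
   The likelihood is the REML (independent-contrast) form, computed in
   C++ in linear time per axis, with retained ordination axes treated as
   independent — they are orthogonal scores, and the full multivariate
   alternative is out of scope. Desk-scale defaults (2e5 iterations, 25%
   burn-in, thinning 20, 2 chains) keep the same estimand as
   production-scale runs; all controls are arguments. The
   One identifiability caveat is intrinsic to the REML form: a shift on
   one child branch of the root is confounded with a shift on its sibling
   (only their summed variance enters the root contrast), so recovery
   checks plant shifts away from the root and users should read
   root-adjacent scalars as a pair. The
   per-axis weights (first axis fixed to resolve scale), and treats the
   stochastic-map identity as a sampled variable with a uniform prior
   over the supplied map pool, so the posterior integrates over mapping
   uncertainty. Convergence reporting uses rank-normalised across-chain
   R-hat (non-split, floored at 1, so identical chains report exactly 1)
   and Geyer initial-monotone-sequence ESS.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure the analysis
assumes: a pure-birth tree scaled to unit height; a habitat-like regime
history under an ER Mk process (default transition rate 0.5 per unit
height — a few changes per lineage, enough for every regime to occupy
appreciable tree length); species shapes as a jaw-like 100-landmark
template (6 fixed anchors, 3 curves of 17 sliding points, 43 surface
points on a bent half-tube) plus isotropic multivariate BM displacements
(per-coordinate SD 0.05 over unit time, about 5% of the template's arc
radius — visible shape change without self-intersection) with
regime-specific rate scalars (default: deep-sea 4x); specimens as
species shapes plus isotropic digitisation noise (SD 0.005, an order of
magnitude below the evolutionary signal) under random similarity
transforms, so GPA genuinely has work to do; trophic levels uniform on
[3.2, 4.6] mirroring the realistic range; and Dirichlet diet
compositions with planted guilds (focal-category concentration 12 against
a flat background). The default study size is 90 species / 145 specimens;
tests run at 8-64 species to stay within a few minutes.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: digitisation error is isotropic and independent
across landmarks (real error is correlated along structures and between
observers); the template is a smooth half-tube rather than real jaw
anatomy; missing landmarks, allometric curvature of shape on size, and
correlated trait covariance across landmarks are absent; trees are known
without error except for the optional branch-length jitter set.

## Numerical choices and degenerate inputs

* GPA requires configurations of rank >= 2 and errors on coincident
  landmarks; rotation signs are fixed by forcing determinant +1.
* Singular bending-energy systems (coincident consensus landmarks) are
  regularised with a warning.
* Ordination axis signs follow the largest-magnitude-loading-positive
  convention, making results deterministic.
* Mk transition matrices use a cached eigendecomposition with a
  scaling-and-squaring fallback for defective rate matrices; conditioning
  on impossible endpoint pairs in mapping raises an error rather than
  looping.
* Zero-length branches in ancestral reconstruction have their
  inverse-length weights capped, with a warning.
* The boundary trophic level 4.2 is classified mesopredator by default
  (`boundary = "TP"` flips it) and flagged, because published usage at
  exactly 4.2 is inconsistent.
* UPGMA delegates to `hclust(method = "average")`; exact ties are broken
  by hclust's convention.
* Bray-Curtis, Wilcoxon tests, Bonferroni correction and Pearson
  correlations delegate to vegan and stats.

## Calibration caveats worth knowing

* Posterior comparison probabilities P(sigma_A > sigma_B) from
  `regime_rate_posterior()` are approximately uniform across null
  replicates when the data are informative — that is what a calibrated
  Bayesian posterior does. Integrating stochastic-map uncertainty pulls
  them toward 0.5; expect occasional extreme values under the null, and
  rely on the overlap criterion (< 0.05) for claims of distinct regimes.
* Feeding sample-PCA scores computed at p >> n into tree-based rate
  models distorts their null distribution (the scores are exactly
  orthogonalised by construction). The rjMCMC tests therefore simulate
  axis scores directly from the model; with real data, retained PaCA/PCA
  axes should be interpreted with this caveat, exactly as in the
  BayesTraits-style workflows this reimplements.
* `meaningful_pcs()` uses an asymptotic chi-square null; with n close to
  p the test is anticonservative and the returned count is a guide, not
  an inference.

## Problem sizes used by the tests and acceptance script

Oracle-equivalence checks run on 2-6-tip trees, triangles and 8-20-row
matrices where brute force is exact. Parameter-recovery runs use 48-64
tips with 4-8 trait dimensions and 5-50 replicates; the acceptance script
uses a 64-species / 96-specimen synthetic study, 20 replicates for regime
ratio and rjMCMC shift recovery, 50 for EB-vs-BM selection, and 200
replicates for permutation-null uniformity. These sizes were chosen so
the full suite completes on one CPU in well under half an hour while
keeping Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

* No mesh handling: surface semilandmarks are not re-projected after
  sliding, and the template-transfer step of mesh-based digitisation is
  out of scope.
* The penalized covariance uses linear shrinkage to the diagonal only
  (no LASSO), and the LOOCV folds reuse full-data coefficients.
* The rjMCMC move set scales single branches; clade-wide scalar moves
  exist in BayesTraits-style software but are not enabled here.
* Wilks' lambda is the only MANOVA statistic (no Pillai).
* External published benchmark values depend on the deposited CT-derived
  data set and are not recomputed here; the acceptance script exercises
  the same estimators on synthetic data instead.
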