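---
title: "Separating direct and spillover pH effects on a soil prokaryotic community: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating direct and spillover pH effects: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own science: the models it
fits, the assumptions behind them, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. The worked numbers in the README and
the `analysis/` scripts are produced by the code itself; nothing here
states a result the tests or the acceptance script do not compute.

## The scientific problem

Liming an acid tropical soil raises pH, but also — mechanically — the Ca
and Mg content (the lime *is* Ca/Mg carbonate), the solubility of Al
(essentially fully precipitated above pH 5.5), Fe, Mn, Cu, Zn and B, the
cation exchange capacity, and, through relieved Al toxicity and improved
nutrition, plant growth and its feedbacks on organic matter and nutrient
cycling. Any observed community shift along the gradient therefore
confounds a *direct* pH effect with these *spillover* routes. The pipeline
operationalizes the separation with a grouped predictor design:

* **G1 (direct 1)** — pH itself;
* **G2 (direct 2)** — Ca and Mg, the liming co-variables;
* **G3 (indirect 1)** — Al, Fe, Mn, Cu, Zn, P, B and CEC;
* **G4 (indirect 2)** — soybean yield, litter, SOM, K and NO₃.

G2–G4 are residualized against pH (per variable, simple OLS on an
intercept and pH), so each retained column measures variation *beyond*
what pH explains; G3 and G4 are then reduced to their two leading
principal components to keep the design at 7 columns for n = 32 samples.

## The joint species distribution model

Both community models share one latent-liability structure. For sample
$i$ and OTU $j$,

$$z_{ij} = \beta_{0j} + x_i^\top \beta_j + h_i^\top \lambda_j +
\varepsilon_{ij},$$

* **presence–absence family**: $y_{ij} = \mathbb 1(z_{ij} > 0)$,
  $\varepsilon_{ij} \sim N(0, 1)$ (probit link, Bernoulli observation);
* **abundance family**: $z_{ij}$ is the observed centered log relative
  abundance of the OTUs present in every sample,
  $\varepsilon_{ij} \sim N(0, \sigma_j^2)$ with conjugate inverse-gamma
  priors on $\sigma_j^2$ (default shape 0.1, rate 0.1).

**Phylogenetic signal.** The loading vector of predictor $k$ over species,
$\beta_{\cdot k}$, has prior $N(0,\ \tau_k^2\, \Sigma_\rho)$ with
$\Sigma_\rho = \rho C + (1-\rho) I$, where $C$ is the tip correlation
matrix of the phylogeny ($C_{jl}$ = shared root-to-tip path length over the
geometric mean of depths) and $\rho \in [0,1]$ interpolates between
independent species responses and fully tree-structured ones. $\rho$ has a
uniform prior on a discrete grid (default 101 equispaced points) and is
drawn from its exact discrete full conditional; the grid is the standard
device because no conjugate update exists in $\rho$. One eigendecomposition
of $C$ serves every grid value, since $\Sigma_\rho$ shares $C$'s
eigenvectors.

**Adaptive predictor scales.** The per-predictor prior scales $\tau_k^2$
are sampled from conjugate inverse-gamma conditionals (prior shape 2, rate
1, prior mean 1 on standardized predictors). This matters for $\rho$: with
a fixed, too-large $\tau^2$ the discrete conditional for $\rho$ is
dominated by the log-determinant of $\Sigma_\rho$ — which is smallest at
$\rho = 1$ for any realistic tree — and the signal estimate collapses to
the boundary whenever the realized loadings are small relative to the
prior scale. Letting $\tau_k^2$ track each column's actual magnitude
removes that artifact; the fixed-scale variant (`tau_sample = FALSE`)
remains available and is what the conjugate closed-form oracle in the test
suite uses.

**Latent factors.** The community-level random effect is a fixed-rank
factor term (default 2 factors) with standard-normal priors on the sample
scores $h_i$ and species loadings $\lambda_j$ — a deliberate
simplification of the multiplicative-shrinkage prior used by full HMSC
implementations, adequate at 32 samples and transparent to test. Residual
associations are reported as the posterior mean of the correlation derived
from $\Lambda\Lambda^\top + \operatorname{diag}(\sigma^2)$ (unit diagonal
variance for the probit family), with a mask of pairs whose sign holds
with at least 95% posterior probability.

**Sampler.** A blocked Gibbs sampler: truncated-normal liabilities
(probit); the *whole* loading matrix $B$ in one exact matrix-normal draw
per iteration, obtained by absorbing $\tau_k$ into the design columns and
$\sigma_j$ into the species side so that the full conditional
diagonalizes in the eigenbases of $X^\top X$ ($P \times P$, trivial) and
of the species-side precision (free for the probit family, one $S \times
S$ eigendecomposition per iteration for the Gaussian family); discrete
$\rho$; Gaussian conditionals for $\Lambda$ and $H$; inverse-gamma
$\sigma_j^2$ and $\tau_k^2$. Defaults: 2 chains × 5000 iterations, 2500
burn-in, thinning 5; split-chain potential scale reduction is reported for
$\rho$ and one species' loadings. Numerical guards: probit truncation
probabilities are clamped to $[10^{-12}, 1-10^{-12}]$; $C$ receives a
$10^{-8}$ jitter only if its smallest eigenvalue is below $-10^{-8}$
(else an error); eigenvalues of $\Sigma_\rho$ are floored at $10^{-10}$.

**Summaries.** Sign-support calls use the inclusive 0.95 boundary on the
posterior probability of a positive (or negative) loading. Variance
partitioning computes, per draw and species, the variance over samples of
each group's partial predictor $X_g \beta_{gj}$ and of the latent part
$H\lambda_j$, normalizes to proportions per species and draw, then
averages; the intercept is constant across samples and so contributes
nothing. Group covariances are not apportioned — the residualized design
makes the groups nearly orthogonal by construction, which is what makes
this simple decomposition meaningful.

**Prediction and cross-validation.** Five balanced random folds; each fold
predicted from a refit on the complement. Probit predictions use the
plug-in probability $\Phi(m/\sqrt{1 + v + \bar\ell})$ with $m, v$ the
posterior mean and variance of the fixed predictor and $\bar\ell$ the mean
latent variance $\lambda_j^\top\lambda_j$ (held-out samples have unknown
factor scores, which are integrated out); a draw-wise averaging variant is
available (`type = "draws"`). Scores: Tjur $R^2$ (mean predicted
probability among presences minus among absences) for occurrence, Pearson
correlation for abundance, averaged unweighted over species; species with
a single observed class are excluded from the mean with a message. The
four reduced designs (G1; G1+G2; G1+G2+G3; G1+G2+G4) are compared on the
*same* folds, making the differences paired.

## Random-forest stage

Each OTU's relative abundance is modelled from the 16 raw covariates (the
raw elements, not the PCA-reduced design — importance is then attributable
to named variables like Al or Cu; a flag allows using the design instead).
Predictor selection is permutation-based: the observed out-of-bag
permutation importance of predictor $k$ is compared with a null
distribution built by refitting the forest on data in which *only column
k* is row-permuted (400 refits per predictor at study scale), with
$p_k = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$ —
never zero — and selection at $p_k \le 0.05$, no multiple-testing
adjustment. If nothing is significant, no model is produced. Performance
is out-of-bag $R^2$ ("variance explained") and a 5-fold cross-validated
$R^2$ ("validation score"; a held-out-correlation variant is available —
the term is operationalized here as CV $R^2$ because it is bounded above
by, and clearly distinct from, the OOB score). Models below validation
score 0.1 are screened out (inclusive boundary: exactly 0.1 is kept, the
rule drops scores *lower than* the threshold). Within each retained model,
selected predictors' final-forest importances (negative values clamped to
0) are normalized to 100%, unselected candidates scoring 0, then averaged
across models; group-level distributions sum within G1–G4 per model.
Forests use 500 trees at study scale, $\lfloor p/3 \rfloor$ candidate
features per split, unlimited depth (regression-forest conventions), all
configurable.

## The synthetic-data generator

The generator emulates the *structure* the analysis assumes, not any
particular field dataset:

* **Design**: 4 doses × 9 plots (36 samples), 3 brands nested in dose with
  a small fixed pH offset; 4 samples under-sequenced so rarefaction to the
  31,000-read target leaves 32.
* **Soil**: pH linear in dose plus Gaussian plot noise, calibrated to span
  ≈ 4.1–6.2; Al a steep decreasing logistic of pH (near zero above 5.5);
  Fe, Mn, Cu, B weakly decreasing; Ca, Mg increasing with dose; yield
  weakly increasing with pH; K, NO₃, SOM, litter pH-independent;
  CEC = H+Al+Ca+Mg+K identically. Slopes and noise were calibrated once so
  that, at large n, the Spearman sign pattern against pH reproduces the
  qualitative screen a liming study shows (Al strongly negative; Fe, Mn,
  Cu, B moderately negative; CEC and yield positive). Gas fluxes are
  pH-independent noise at typical field magnitudes, and double as the
  ground truth for the chamber-series round trip.
* **Community**: species loadings on the 16 standardized covariates drawn
  per predictor from $N(0, s_g^2(\rho C + (1-\rho) I))$ via the Cholesky
  factor (group scales $s_g$, defaults G1 0.8, G2 0.25, G3 0.18, G4 0.12 —
  pH dominant, indirect groups spread over more covariates); latent
  factors with loading scale 0.5; occurrence by probit thresholding;
  species baseline occupancy drawn with probit-scale heterogeneity
  (sd 1.5, centered so the marginal mean stays at `occupancy_base`) plus a
  25% "core" fraction of near-ubiquitous taxa — the core/satellite
  occupancy spectrum of real 16S surveys, and the feature that gives the
  abundance model a non-trivial present-in-all-samples set. Setting
  `occupancy_sd = 0` switches the baseline off entirely (homogeneous
  null), which is what the controlled experiments in the test suite use.
  Log abundance shares the occurrence linear predictor (species that
  respond in occurrence respond in abundance) with its own species
  baseline and residual sd 0.5; counts are multinomial at each sample's
  assigned depth, zero for non-occurring taxa.
* **Not emulated**: sequencing error, chimeras, taxonomy, compositional
  artifacts beyond the multinomial, spatial autocorrelation, temporal gas
  dynamics (chamber series are linear accumulation only). Block effects
  exist as a knob (`block_sd`) with default 0 — the field design gives no
  basis for a magnitude. Passing tests therefore demonstrate correctness
  of the machinery under the stated generative assumptions, not robustness
  to the full messiness of real surveys.

## Open choices and their resolutions

* **Pearson vs Spearman** ("whichever fits better") is operationalized as
  the larger absolute coefficient; both are always retained in the output.
* **Spearman p-values**: t approximation for n ≥ 10, exact rank-statistic
  null below.
* **Residualization** is per-variable simple regression on pH; Ca and Mg
  separately.
* **PCA on correlation**, not covariance — the groups mix units
  (cmolc dm⁻³, mg dm⁻³, kg ha⁻¹); deterministic sign convention (dominant
  loading positive).
* **Design columns standardized** so the exchangeable prior scales are
  comparable; back-transform metadata retained.
* **Lime-brand fixed effects** are not in the default design (the
  7-variable design is exhaustive); the sample table carries brand for
  sensitivity checks.
* **Rarefaction** is a single recorded-seed draw without replacement;
  negative PCoA eigenvalues are reported, not corrected; `envfit` uses the
  first two axes with 999 permutations by default.
* **Recovery experiments** for the phylogenetic signal fit the model on
  the full 16-covariate generative design rather than the 7-column
  reduction: the reduction discards covariate directions whose
  phylogenetically structured effects would otherwise act as
  tree-correlated residual noise, biasing $\rho$ upward — a model-mismatch
  question worth knowing about, but separate from the sampler-correctness
  question the recovery test isolates.

## Problem sizes used in tests and the acceptance script

Reported numbers are computed at desk scale, chosen once: the default
36-sample × 150-OTU study for end-to-end runs; 40 OTUs × 60 samples ×
10 seeds per condition for ρ-recovery (1500 iterations, 500 burn-in);
conjugate checks on 5 species × 40 samples with 2 × 4000 iterations;
forest error-control at 200 null replicates × 8 predictors × 100
permutations with 50-tree forests (tree count does not enter the validity
of the permutation test, only its variance); the acceptance script fits
both JSDM families with 2 × 1500 iterations and models 10 OTUs in the
forest stage. MCMC lengths are small by production standards; the
split-chain diagnostics are reported with every fit so longer runs can be
judged the same way.

## Known limitations

* The Gaussian family's per-iteration species-side eigendecomposition is
  $O(S^3)$; at the study's 271 omnipresent OTUs this is ~20 ms per
  iteration — fine for thousands of iterations, but the probit family is
  markedly cheaper.
* Fixed-rank factors cannot shrink their own dimension; choose
  `n_factors` by comparing cross-validated scores.
* Variance partitioning ignores between-group covariance; it is
  interpretable because the design is residualized, and would need a
  Shapley-style allocation otherwise.
* The permutation selection refits `n_perm` forests per predictor; at 400
  permutations × 16 predictors × 500 trees per OTU this is the dominant
  cost at study scale and is embarrassingly parallel across OTUs.
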