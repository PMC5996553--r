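# soilspill

Soil pH is the master variable of soil microbial ecology, but a pH gradient
never acts alone: changing pH also changes the solubility of Al, Fe, Mn, Cu,
Zn, B and P, the cation exchange capacity, and — through plant growth —
litter, organic matter and nutrient cycling. `soilspill` implements an
analysis pipeline that *separates the direct effect of pH from these
"spillover" (indirect) effects* on a prokaryotic community observed along a
liming gradient, together with a synthetic-data module that emulates such a
study (4 lime doses × 9 replicate plots, pH ≈ 4.1–6.2, 16S OTU table
rarefied to 31,000 reads) so that every stage of the pipeline has a
ground-truth recovery test.

The pipeline has five stages, each exposed as plain R functions and driven
by the numbered scripts in `analysis/`:

1. **Soil chemistry** — static-chamber gas fluxes
   (`f = ΔC/Δt · V/A · m/Vm`, with `Vm = 22.414 · T/273.15`), CEC as the
   exchangeable-cation sum H+Al+Ca+Mg+K, Simpson diversity, and a
   correlation screen that reports Pearson *r* or Spearman *ρ* (whichever
   fits better) and flags pairs with |coef| > 0.4 and P < 0.05.
2. **Community matrices** — rarefaction without replacement (samples below
   the target depth are excluded), unweighted UniFrac, PCoA, and `envfit`
   vector fitting with permutation tests.
3. **Predictor design** — the conceptual model's four covariate groups:
   G1 = pH; G2 = Ca, Mg (liming co-variables); G3 = element availability
   (Al, Fe, Mn, Cu, Zn, P, B, CEC); G4 = plant growth and nutrient cycling
   (yield, litter, SOM, K, NO₃). G2–G4 are residualized against pH so they
   measure influences *beyond* pH, and G3/G4 are reduced to their two
   leading principal components, giving a 7-column design.
4. **Joint species distribution model** (the core of the package) — a
   hierarchical multivariate probit/Gaussian model fitted by a blocked
   Gibbs sampler. For sample *i* and OTU *j*,

   ```
   z_ij = x_i' β_j + h_i' λ_j + ε_ij
   ```

   with occurrence `y_ij = 1(z_ij > 0)` (probit family) or `z_ij` the
   centered log relative abundance (Gaussian family). The species loadings
   are tied across the phylogeny: each predictor's loading vector over
   species has prior `N(0, τ²_k (ρC + (1−ρ)I))`, where `C` is the tip
   correlation matrix of the 16S tree and `ρ ∈ [0,1]` — sampled on a
   discrete grid — measures the strength of the phylogenetic signal.
   `h_i` and `λ_j` are latent community factors capturing residual
   co-occurrence. Summaries: 95%-posterior sign-support calls per OTU ×
   predictor, variance partitioning over G1–G4 and the latent term,
   residual association matrices, fivefold cross-validation (Tjur R² /
   correlation) of the full and four reduced designs.
5. **Random forests** — each OTU's abundance modelled from the 16 raw
   covariates, with permutation-based predictor selection (each candidate
   is refitted against a null built by permuting only that predictor),
   out-of-bag R² and a cross-validated validation score, a 0.1
   validation-score screen, and per-model importance percentages averaged
   over the retained models.

## Worked example

```r
library(soilspill)

cfg <- sim_config(seed = 1)              # 4 doses x 9 plots, 150 OTUs
sim <- simulate_dataset(cfg)
rr  <- rarefy(sim$counts, cfg$read_depth_target, seed = 2)
soil <- sim$soil[rownames(rr$counts), ]

X    <- build_design(soil)               # pH, Ca*, Mg*, G3_1, G3_2, G4_1, G4_2
keep <- pa_filter(rr$counts, 10, 10)     # OTUs variable in occurrence
C    <- phylo_correlation(sim$tree)

fit <- jsdm_fit((rr$counts[, keep] > 0) * 1, X, C[keep, keep],
                jsdm_spec("probit", n_factors = 2, seed = 3))
fit
#> JSDM fit (probit family)
#>   32 samples x 46 species, 7 predictors (+intercept), 2 factors
#>   1000 retained draws (2 chains)
#>   phylogenetic signal rho: 0.820 (0.580-0.990)
#>   max split-Rhat: 1.007

variance_partition(fit)$community
#>         G1         G2         G3         G4     latent
#> 0.32322575 0.10208392 0.09067282 0.09288230 0.39113521
```

The generator planted `rho_true = 0.7`: the posterior interval covers it,
and pH (G1) carries the largest predictor-group share of explained
variance, with the residualized indirect groups behind it — the same
reading the pipeline is designed to produce on field data. Stage scripts
print the rest of the story (`analysis/05_jsdm.R`: cross-validated Tjur R²
rises from 0.14 with pH alone to 0.18 with the full design;
`analysis/06_rf.R`: pH and Al top the importance ranking).

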