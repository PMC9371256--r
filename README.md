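# crossfc

Cross-modal mapping of band-limited electromagnetic and haemodynamic brain
connectivity.

Electromagnetic (MEG) and haemodynamic (fMRI) functional connectivity view
the same cortical networks through different physiological windows.
`crossfc` is an R package for researchers who want to relate the two on a
common parcellation, region by region. Its core is the regional multilinear
model: for each region *i*, the haemodynamic connectivity profile (row *i*
of the FC matrix, self-connection excluded) is regressed on the region's
electromagnetic profiles in the six canonical frequency bands (δ 2–4, θ 5–7,
α 8–12, β 15–29, lo-γ 30–59, hi-γ 60–90 Hz):

    FC_i = b1·FC(δ)_i + b2·FC(θ)_i + b3·FC(α)_i + b4·FC(β)_i
         + b5·FC(lo-γ)_i + b6·FC(hi-γ)_i + b0

Each regional fit is summarized by adjusted R² (n = N−1 observations,
p = 6), giving a cortex-wide *cross-modal correspondence map*. Around that
core the package provides:

- **Connectivity estimation** from parcellated time series: amplitude
  envelope correlation with pairwise orthogonalization (leakage
  correction), phase-locking value, Pearson haemodynamic FC, and the
  source SNR formula `10·log10((a²/N)·Σ b_k²/s_k²)`.
- **Dominance analysis** of the six bands (all 2⁶−1 = 63 predictor
  subsets; percent relative importance per band) with one-way ANOVA and
  Bonferroni-corrected pairwise contrasts across regions.
- **Validation**: distance-dependent region-level cross-validation (75%
  closest regions to a source region train, 25% test, one split per
  candidate source) and leave-one-subject-out cross-validation.
- **Spin permutation inference**: hemisphere-respecting random rotations of
  the spherical parcel geometry with nearest-parcel reassignment, two-tailed
  p_spin, and Benjamini–Hochberg FDR.
- **Cortical context**: diffusion-map principal functional gradient,
  structure–function coupling, laminar depth-profile associations, robust
  sigmoid / unit-interval expression normalization, and differential
  stability across donors.
- A **synthetic-data generator** that plants known mixing weights, a
  hierarchy-graded noise profile with an analytic target-R² map, coupled
  time series, laminar profiles, an expression panel, and a structural
  network — so every stage of the pipeline can be validated against ground
  truth. See the methods vignette (`vignettes/crossmodal-mapping.Rmd`) for
  the model and the design choices.

## Worked example

```r
library(crossfc)

cfg   <- synthetic_config(n_parcels = 100, seed = 1)
geom  <- make_geometry(cfg$n_parcels, seed = 1)
bands <- make_band_fc_set(geom, cfg)
sim   <- make_crossmodal_truth(bands, geom, cfg)   # haemo matrix + ground truth

fits <- fit_all_regions(sim$haemo, bands)
round(range(fits$adj_r2), 3)
#> [1] 0.034 0.859

cor(fits$adj_r2, sim$truth$target_r2, method = "spearman")
#> [1] 0.959

spins <- generate_spins(geom, n_spin = 1000, seed = 2)
test  <- spin_pvalue(fits$adj_r2, sim$truth$hierarchy, spins)
c(r = round(test$r, 3), p_spin = round(test$p_spin, 4))
#>      r p_spin
#> -0.959  0.002

dom <- dominance_all_regions(sim$haemo, bands)
round(colMeans(dom$contributions), 1)
#>  delta  theta  alpha   beta lgamma hgamma
#>   10.9   17.1   18.4   31.0   10.7   11.9

fit_global_model(sim$haemo, bands)$adj_r2
#> [1] 0.381
```

Reading the numbers: regional fits span near 0 to 0.86 — the generator
grades noise along a synthetic unimodal–transmodal hierarchy, so cross-modal
correspondence declines along it. The fitted map recovers the planted
target-R² map (Spearman 0.96) and anticorrelates with the hierarchy
(r_s = −0.96), significant against 1,000 spatial-autocorrelation-preserving
spins (p_spin = 0.002). Dominance analysis attributes the largest mean
contribution to the beta band (31%), as planted by the default weight
profile, and the single global model explains far less variance (0.38 here)
than the best regional fits — the motivation for modelling regions
separately.

An end-to-end run (`run_pipeline(analysis_config(...))`) chains generation,
fitting, dominance, cross-validation, nulls, and context statistics, and
writes delimited-text maps plus a JSON summary with full provenance (seed,
sizes) to an output directory.

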