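---
title: "Mapping band-limited electromagnetic connectivity onto haemodynamic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping band-limited electromagnetic connectivity onto haemodynamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfc)
```

## The scientific problem

Haemodynamic functional connectivity (FC), measured as the Pearson
correlation between regional fMRI time series, and electromagnetic FC,
measured from MEG as band-limited amplitude envelope correlation (AEC) or
phase-locking value (PLV), view the same cortex through very different
physiological windows. `crossfc` implements a region-wise account of how the
two relate: for every cortical region $i$, the haemodynamic connectivity
profile (row $i$ of the FC matrix, self-connection excluded) is modelled as
a linear combination of the region's electromagnetic profiles in the six
canonical frequency bands,

$$
\mathrm{FC}_i \;=\; b_1\,\mathrm{FC}(\delta)_i + b_2\,\mathrm{FC}(\theta)_i
+ b_3\,\mathrm{FC}(\alpha)_i + b_4\,\mathrm{FC}(\beta)_i
+ b_5\,\mathrm{FC}(l\gamma)_i + b_6\,\mathrm{FC}(h\gamma)_i + b_0 ,
$$

fitted by ordinary least squares on the $N-1$ off-diagonal entries and
summarized by adjusted $R^2$ (Ezekiel's formula with $p = 6$). The map of
regional adjusted $R^2$ is the *cross-modal correspondence map*. Around this
core the package provides

* a single *global* model on the $N(N-1)/2$ upper-triangle edges, and
  single-band regional models for comparison;
* *dominance analysis*, decomposing each regional fit over all $2^6-1 = 63$
  predictor subsets into per-band contributions, with a one-way ANOVA and
  pairwise contrasts (Bonferroni over the 15 band pairs, pooled-SD Cohen's
  $d$) across regions;
* *distance-dependent cross-validation* (train on the 75% of profile
  entries closest to a source region, test on the remaining 25%, one split
  per possible source) and *leave-one-subject-out* cross-validation;
* *spin permutation tests*: hemisphere-respecting random rotations of the
  spherical parcel coordinates with nearest-parcel reassignment, giving
  spatial-autocorrelation-preserving nulls and two-tailed
  $p_\mathrm{spin} = (1 + \#\{|r_0| \ge |r|\})/(n_\mathrm{spin}+1)$;
* *cortical context* statistics: the principal functional gradient by
  diffusion-map embedding, structure–function coupling, laminar
  depth-profile associations with BH–FDR across depths, and gene-expression
  normalization (robust sigmoid, unit rescaling) with differential
  stability across donors.

Because the recordings this methodology was designed for are access
restricted, the package ships a first-class synthetic-data generator that
plants every quantity the pipeline is supposed to recover.

## What the generator emulates

`make_geometry()` places parcels quasi-uniformly on a unit sphere with a
Fibonacci lattice, mirrored across the midline so left and right hemisphere
parcels correspond — the property the mirrored spin rotations rely on.
Coordinates are in unit-sphere units; all length scales below are on that
scale.

`make_band_fc_set()` builds each band matrix as
$0.5\,e^{-d/\lambda}$ (distance decay, default $\lambda = 0.8$) plus a
band-specific smooth rank-one modulation (amplitude 0.15) and symmetric
Gaussian noise (SD 0.02), clipped to $[-1, 1]$ with a zero diagonal. The
decay reproduces the ubiquitous distance dependence of cortical
connectivity; the modulation is what makes the six bands distinguishable
predictors.

`make_crossmodal_truth()` plants the regional model. Mixing weights vary
linearly along a synthetic unimodal–transmodal hierarchy — the
rank-uniformized draw of a smooth Gaussian process, so hierarchy positions
have a uniform marginal — with alpha/beta strongest toward the unimodal end
and slow rhythms gaining toward the transmodal end, echoing where fast and
slow rhythms dominate in cortex. Row-wise mixtures are symmetrized by
averaging, so edge $(i,j)$ carries the mean of both endpoint weight
profiles. Noise is a symmetric field with entry variance
$\mathrm{sd}_i\,\mathrm{sd}_j$. This multiplicative coupling is a deliberate
choice: with additive row noise symmetrized by averaging, every region's
noise floor contains the cortex-wide mean noise variance, which makes
strongly graded correspondence maps impossible to plant; under the
multiplicative model a clean region adjacent to noisy ones stays clean, and
any non-negative per-region noise-variance profile is exactly realizable.

In the default `"graded"` profile the generator specifies the *expected
variance explained* per region — linear in the hierarchy from 0.8 down to
0.05, a range chosen to match the magnitude of regional fits reported for
real cortex — and solves for the noise scales that realize it (a fast fixed
point, since row $i$'s mean noise variance is
$\mathrm{sd}_i \cdot \overline{\mathrm{sd}}_{-i}$). The analytic target is

$$
R^2_{\mathrm{target},i} \;=\; \frac{ev_i}{v_i + nv_i},
$$

with $v_i$ the variance of the noiseless symmetrized signal row, $ev_i$ the
part of it explainable by the band profiles (computed by a deterministic
noise-free fit: region-varying weights take the symmetrized mixture
slightly outside the regional model class, and $ev_i$ absorbs that misfit
exactly), and $nv_i$ the mean noise variance of the row. This is the
recovery oracle used throughout the tests: the fitted adjusted-$R^2$ map
should track `target_r2` (Spearman $\ge 0.9$ at $N = 200$) and anticorrelate
with the hierarchy.

The remaining generators plant: per-subject ensembles (group matrix plus
symmetric noise); laminar profiles over 50 depths whose loading on an
anchor map peaks at a configurable depth (all depths share one nuisance
map, so the $|r_s|$ profile over depth follows the loading curve
deterministically); a multi-donor expression panel with tunable cross-donor
consistency and one designated gene whose latent pattern has a configurable
Gaussian-scale correlation with the anchor; a sparse non-negative
structural matrix with distance-decaying edge probability and weight; and
narrowband time series with planted envelope-coupled pairs
(constant-amplitude carriers sharing a slow envelope, so leakage-corrected
AEC recovers the coupling) and phase-locked pairs (phase-shifted copies,
PLV $\approx 1$).

What the generator does *not* emulate: biophysical source mixing and field
spread (leakage appears only as explicit zero-lag admixture in fixtures),
1/f spectra and cross-frequency coupling, heavy-tailed FC distributions,
subject-level structured variability, or realistic geometry beyond a
sphere. Passing tests therefore certify the estimators and their
statistical calibration, not the physiological claims one could make on
real recordings.

## Numerical and design choices

* **Filtering.** Band-pass is a zero-phase forward–backward 4th-order
  Butterworth; zero phase preserves envelopes and instantaneous phases.
  Envelopes and phases come from the FFT-based analytic signal. Two cycles
  of the band's low edge are trimmed at each end before correlating, to
  suppress filter transients.
* **Leakage correction.** Orthogonalization is the time-domain least-squares
  residual, applied in both directions and averaged. It removes zero-lag
  *collinear* leakage exactly (a duplicated signal yields a zero residual,
  reported as 0 with a warning); it cannot remove an independent common
  additive source, and on strongly coupled pairs it is conservative — both
  are properties of the method, not of this implementation.
* **Regression.** Profiles enter on their raw correlation scale (adjusted
  $R^2$ is scale invariant); negative FC values are retained;
  rank-deficient designs fall back to a minimum-norm solution with a
  warning rather than failing a sweep.
* **Dominance.** Incremental gains are averaged within each subset size and
  then across sizes; gains use adjusted $R^2$ (the scale on which the full
  models are compared), negative gains are kept, and percent importance is
  normalized by the summed total dominance, which equals the full-model
  fit — keeping the decomposition property testable. An `"unadjusted"`
  switch exists because exact additivity for orthogonal predictors holds
  only on unadjusted $R^2$.
* **Cross-validation.** "Pseudorandom" source selection is resolved as
  deterministic enumeration of all $N-1$ sources; train size uses floor
  rounding; per-split performance is the Pearson correlation between
  empirical and predicted profiles. In the subject-level variant the
  held-out subject's own band profiles serve as test predictors — an
  interpretation choice, since either reading is defensible.
* **Spin tests.** Rotations are Haar-uniform (QR of a Gaussian matrix with
  sign fixing and a determinant flip), verified against the
  $(\theta - \sin\theta)/\pi$ angle law. The rotation is applied to one
  hemisphere and its mirror image to the other; duplicates from
  nearest-parcel reassignment are allowed. The $+1$ in numerator and
  denominator keeps $p_\mathrm{spin} > 0$. Rank correlation is the default
  association measure.
* **Gradient.** Each row keeps its top 10% of off-diagonal values (ties by
  index order), cosine similarity is clipped at zero to give a positive
  affinity, and the diffusion map uses $\alpha = 0.5$ with
  eigenvalue-scaled ("automatic") diffusion time. Regions with no surviving
  connections are an error. If the affinity graph splits into components
  (as hard planted partitions do after thresholding), the unit eigenvalue
  is degenerate; the package rotates that eigenspace so the trivial
  direction comes first and the leading non-trivial component is the
  component contrast, and warns. The gradient's sign is aligned to an
  anchor map when one is given, otherwise the largest-magnitude entry is
  made positive.
* **Expression.** The "normalized interquartile range" of the robust
  sigmoid is IQR/1.349, the normal-consistent scaling. The module consumes
  an already region-aggregated panel; probe-level processing is out of
  scope.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
unit fixtures use 10–100 parcels, recovery checks 200 parcels (the
regional-fit scale of a low-resolution cortical atlas, $n = 199$
observations per fit), structural checks 400 parcels, spin calibration
1,000 map pairs against 500 spins on 100 parcels, and the pipeline demo
200 parcels with 1,000 spins. These sizes were chosen so each planted
effect is detected with a comfortable margin while the whole suite runs in
well under a minute.

## Known limitations

Adjusted-$R^2$ estimates at $n = 199$ carry sampling noise of roughly 0.05,
which bounds how sharply the target map can be recovered at that scale.
Dominance percentages are only weakly identified when band matrices are
nearly collinear, and symmetrization genuinely shares credit across
hemispheres for cross-hemisphere edges. The spin test's calibration is
verified for smooth Gaussian-process maps; maps with qualitatively
different spatial statistics may be mildly miscalibrated, as is true of
spin tests generally.
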