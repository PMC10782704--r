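---
title: "Evaluating pseudo-CT for brain SRT: models and methods in pctqa"
author: "pctqa maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pseudo-CT for brain SRT: models and methods in pctqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctqa)
```

## The problem

MRI-only radiotherapy planning replaces the planning CT with a pseudo-CT
(pCT): a Hounsfield-unit volume synthesised from MRI so that dose can be
calculated without a CT scan. Before a pCT can stand in for the planning CT
in stereotactic radiotherapy (SRT) of small brain lesions, the two images
must be shown to be interchangeable along every axis on which they are
used: raw HU values inside each structure, the dose distributions
recalculated on each image, the dose-volume-histogram (DVH) metrics and 3-D
gamma passing rates derived from those doses, the radiomic features
extracted from each image, and the predicted clinical effect (tumour
control probability, TCP; normal-tissue complication probability, NTCP).

`pctqa` implements that full evaluation chain as a reusable, tested
pipeline. Because clinical image sets of this kind are not freely
distributable, the package also ships a synthetic phantom generator that
emulates the *deviation structure* between a planning CT and a CNN-type
pCT, so every stage of the pipeline is exercisable and testable end-to-end
without patient data.

## The phantom generator: what it emulates, and what it does not

`generate_case()` builds a head-like phantom: a soft-tissue ellipsoid
(~40 HU) inside a bone shell (~1000 HU) inside air (−1000 HU), with
brainstem and spinal-cord cylinders, lens/optic-nerve/chiasm ellipsoids,
and 1–4 spherical gross tumour volumes (GTVs) of 0.5–27.3 cm³ placed
randomly in the brain without overlapping any organ at risk. Each planning
target volume (PTV) is its GTV expanded by an isotropic 2 mm margin,
implemented as Euclidean-distance thresholding rather than a fixed
structuring element so the margin is independent of voxel spacing.

The emulated study conditions are fixed as defaults and are not tuning
knobs:

* lesion count 1–4 with cohort frequencies (25, 4, 4, 1)/34; lesion
  volumes log-normal with median 3.4 cm³, clipped to [0.5, 27.3] cm³;
* prescriptions 1 × (20–24) Gy, 3 × 7 Gy or 5 × 6 Gy with cohort
  frequencies (14, 14, 5)/33, and the prescription held at ~80% of the
  maximum dose;
* dose grids 1.25 mm isotropic;
* a pseudo-CT whose mean HU sits slightly below the CT
  (`hu_mean_offset = -8` HU) with additive noise (`noise_sd = 10` HU),
  both chosen so that the soft-tissue mean absolute HU deviation stays
  below the 15 HU regime the pipeline is designed to detect, and a raised
  HU minimum (below).

### The pseudo-CT deviation model

`generate_pct()` applies three perturbations inside the body outline (air
is untouched, so the outline is identical by construction):

1. a constant negative HU offset, so the CT mean exceeds the pCT mean;
2. a *floor raise*: each voxel is lifted toward a Gaussian-smoothed copy of
   the CT (`hu_min_smoothing_sigma = 2` mm), but only lifts below 50 HU are
   applied so tissue boundaries are not smeared. This reproduces the
   characteristic pCT artefact that local HU minima are attenuated because
   the generating network smooths low-signal detail. The magnitude of this
   artefact is not quantified anywhere we could anchor it, so the sigma is
   an explicit, documented free parameter;
3. independent Gaussian noise.

### The analytic dose model

The phantom dose is deliberately *not* a beam model — treatment-planning
dose calculation is out of scope, and only the relative CT-vs-pCT
evaluation machinery is being exercised. Per lesion the dose is

$$D(\mathbf{x}) = D_{max} \exp\!\big(-(d/\sigma)^2\big),\qquad
D_{max} = \mathrm{PD}/0.8,$$

where $d$ is the distance outside an isodose core placed
$\delta = \sigma\sqrt{\ln 1.25}$ inside the PTV surface and $\sigma$ = 3 mm
mimics the rapid stereotactic fall-off. This placement makes the maximum
dose sit at the lesion centre, puts the prescription (80%) isodose exactly
on the PTV surface, and gives the PTV DVH a continuous shoulder so that
D95%-renormalisation is well-posed (with a dose that is uniform inside the
PTV, D95% degenerates to the maximum and the 95% condition cannot be
meaningfully verified). Multi-lesion doses sum.

The pCT dose is derived from the CT dose by a small random multiplicative
scale (s.d. 0.15%), a random sub-millimetre rigid shift (s.d. 0.2 mm per
axis), and optional noise — the same deviation channels that plan
recalculation and rigid dose transfer introduce in practice. Because the
perturbation is synthetic and known, planted-effect recovery can be tested
(see below).

What the phantom does **not** emulate: realistic beam/arc geometry, couch
and collimator effects, MRI distortion, registration error between
independently acquired images, heterogeneity corrections, or the
texture of real brain CT beyond stationary Gaussian noise. Consequently,
passing tests demonstrate that the *measurement machinery* is correct and
sensitive at realistic deviation magnitudes — not that any particular
clinical pCT product is safe.

## HU and DVH metrics

`hu_summary()` reports max/min/mean/SD (population SD, divisor $N$; the
convention is stated because either choice is defensible) and volume per
structure; structures under 5 voxels are flagged unreliable, the analogue
of the small-lens caveat. `hu_deviation()` returns signed and absolute
differences, CT minus pCT.

`compute_dvh()` bins masked dose values into a differential histogram
(default bin width 0.01 Gy) and an exact cumulative "volume at or above
dose" curve; voxels are point samples at their centres. `dose_at_volume()`
(Dx%) and `dose_at_absolute_volume()` (D 0.1 cm³) invert the cumulative
curve with linear interpolation between edges, so all quantile-type
metrics are accurate to one bin width; Dmax/Dmin are voxel extremes. The
conformity surrogates are body-volume ratios,
$R_{100\%} = V_{100\%}/V_{PTV}$ and $R_{50\%} = V_{50\%}/V_{PTV}$. PTV
metric panels rescale each dose grid so the PTV's D95% equals the
prescription (`normalize_to_d95()`) and report Dmin/Dmax/Dmean divided by
the prescription; organ-at-risk panels stay in Gy and are never
renormalised. Masks living on a different grid are resampled
nearest-neighbour onto the dose geometry, always resampling the evaluated
object onto the reference geometry.

## 3-D gamma index

For reference voxel $\mathbf{r}$ the gamma index is

$$\gamma(\mathbf{r}) = \min_{\mathbf{e}}
\sqrt{\frac{\|\mathbf{e}-\mathbf{r}\|^2}{\Delta d^2} +
\frac{\big(D_e(\mathbf{e})-D_r(\mathbf{r})\big)^2}{\Delta D^2}},$$

with $\Delta d$ the distance criterion and $\Delta D$ the dose criterion
times the reference maximum (global mode) or the local reference dose
(local mode). Reference voxels below 10% of the reference maximum are
excluded; both the threshold rule ("reference voxel below threshold") and
the global normalisation point (grid maximum, not prescription) are
configuration switches because commercial tools are not explicit about
either.

The minimisation is the delicate part: the evaluated dose is trilinear
within each grid cell, and in local mode at modest doses the gamma surface
develops valleys only a few hundredths of a millimetre wide, which
defeats naive lattice searches. `gamma_map()` therefore uses certified
branch-and-bound over the interpolation cells: a trilinear function
attains its extremes at box corners, so every axis-aligned box carries an
exact lower bound on $\gamma^2$ (distance-to-box plus dose-gap-to-corner
range). Boxes that cannot improve the running best by more than
`tol_gamma` (default 0.005) are pruned; the rest are subdivided,
nearest-first so the best converges before distant boxes are visited.
Boxes that could still flip the pass decision at $\gamma = 1$ are always
refined, so the passing rate is exact at any tolerance — pass-rate tables
exploit this with a relaxed tolerance for speed (`exact_above = 1.01`,
`tol_gamma = 0.05`) without changing any rate. Every reported value is
achieved by an explicit candidate point whose offset is returned, which
the test-suite re-verifies with an independent interpolation, alongside a
comparison against an exhaustive fine-lattice search.

## Radiomic features

`extract_features()` computes the 107 "original image" features in seven
families: 18 first-order, 14 three-dimensional shape, 24 GLCM, 16 GLRLM,
16 GLSZM, 5 NGTDM and 14 GLDM. The 18 + 14 + 24 + 16 + 16 + 5 + 14
decomposition is the only one consistent with the printed total of 107,
so the "2D/3D shape" family is implemented as the 14 3-D shape features.

Numerical conventions, all configuration-exposed where the upstream
convention is not fixed:

* fixed-bin-width discretisation relative to the masked minimum, default
  25 HU, no resampling before extraction;
* texture matrices over the 13 unique 3-D directions at Chebyshev
  distance 1, symmetric accumulation, per-direction features averaged
  (GLCM, GLRLM); GLSZM zones are 26-connected components; GLDM dependence
  counts neighbours within `alpha = 0` grey levels;
* shape surface area and mesh volume use the voxel-boundary (exposed-face)
  mesh. This is exact for axis-aligned boxes and overestimates the area of
  smooth bodies by the staircase factor; mesh and voxel volume coincide
  under this convention. Axis lengths come from the principal components
  of the voxel-centre cloud ($4\sqrt{\lambda_i}$);
* degenerate situations (single grey level, single voxel, no valid voxel
  pairs along a direction) yield `NA` with a `degenerate` flag, never a
  silent drop.

`compare_features()` performs the paired Wilcoxon test per feature after
removing features for which any case produced a degenerate or non-finite
value — the footprint of organs too small to support texture matrices,
which is exactly the regime in which whole texture families (NGTDM, GLCM)
drop out. A median ± k·IQR screen is available as an alternative rule.

## Radiobiological models

All models run on EQD2-converted differential DVHs: each bin dose $D_i$ is
converted with $\mathrm{EQD2} = D_i\,(d_i + \alpha/\beta)/(2 +
\alpha/\beta)$, $d_i = D_i/n_{fx}$, i.e. uniform fractionation is assumed
per bin. gEUD is the power mean $\big(\sum_i v_i D_i^{a}\big)^{1/a}$
(the $a = 0$ geometric-mean limit is deliberately not implemented and
errors instead).

* **TCP** uses the EUD-logistic form
  $\mathrm{TCP} = \big(1 + (\mathrm{TCD}_{50}/\mathrm{EUD})^{4\gamma_{50}}\big)^{-1}$.
  The source this pipeline follows cites but does not print its TCP
  equation, so the standard EUD-logistic with the $\gamma_{50}$ slope
  identity was chosen; the two definitional anchors — TCP = 1/2 exactly at
  EUD = TCD$_{50}$, and slope $\gamma_{50}$ per 1% dose change at that
  point — are enforced by the acceptance tests, which is precisely what
  the parameter definitions promise.
* **NTCP** uses Lyman–Kutcher–Burman:
  $D_{eff} = \big(\sum_i v_i D_i^{1/n}\big)^{n}$,
  $\mathrm{NTCP} = \Phi\!\big((D_{eff} - \mathrm{TD}_{50})/(m\,
  \mathrm{TD}_{50})\big)$. $D_{eff}$ is computed with the maximum dose
  factored out so small $n$ cannot overflow; the $n \to 0$ serial-organ
  limit converges like $n \log v_{max}$, which the tests check at
  decreasing $n$.

The shipped parameter file (`inst/extdata/radbio_params.json`) uses
$\alpha/\beta$ = 3 Gy for normal tissues and probit-volume parameters in
the ranges long used for the serial brain organs, plus a tumour set
(TCD$_{50}$ = 24 Gy, $\gamma_{50}$ = 1.5, gEUD exponent $a$ = −10) aimed at
1-year local control of brain metastases. These are placeholders for
methodological testing, marked non-clinical in the file itself; the loader
validates completeness and honours an `exclude` flag, which is set for the
spinal cord by default because LKB does not reliably predict cord
tolerance at stereotactic doses.

## Statistics

`wilcoxon_signed_rank()` drops zero differences (the original rule; a
Pratt variant is available), and for up to 15 nonzero pairs computes the
two-sided p-value by exact convolution over the doubled mid-ranks — exact
enumeration of all $2^n$ sign assignments, valid under ties, verified
against brute-force enumeration in the tests. Beyond that it switches to
the normal approximation with mid-rank (tie-corrected) variance and
continuity correction. `spearman_corr()` is Pearson on mid-ranks with the
t-approximation p-value; `normality_check()` records the Shapiro–Wilk
pre-check that motivates the nonparametric choice but never switches tests
automatically. Raw p-values are reported without multiplicity correction,
matching the presentation this pipeline mirrors; stars are `*` < 0.05,
`**` < 0.01, `***` < 0.001. `mad_paired()` is the mean absolute pairwise
deviation.

`correlation_report()` assembles the full Spearman matrix over the
case-level factor table (lesion count, fraction number, PTV volume,
perturbation-profile code, HU deviations, DVH deviation, gamma rates) with
per-cell stars; constant or unavailable columns are flagged, not fatal.
`build_report()` writes the entire bundle (HU, DVH, gamma, TCP/NTCP,
factors, correlations) as deterministic CSVs plus a JSON summary.

## Problem sizes and design checks

The package's own verification uses desk-scale problems chosen to exercise
every code path: unit fixtures of 4³–20³ voxels with closed-form answers;
a 64³ (1.5 mm) single-case phantom for radiomics and D95 renormalisation;
20-case cohorts on a 96³ grid (1.25 mm dose grids of ~115³) for gamma
criteria monotonicity and the HU regime; and 50 replicates of 12-case
cohorts on a 48³ (2 mm) grid, with lesion volumes capped at 4 cm³ so all
balanced lesion counts remain placeable, for planted-effect recovery. The
planted effect adds 0.5% dose scale per additional lesion against a 0.15%
random scale noise — a deliberately strong monotone signal whose recovery
(positive, significant lesion-count × DVH-deviation cell) should succeed
in essentially every replicate if the correlation layer is wired
correctly. Two analysis details matter there: the factor table must
compare *raw* (un-renormalised) DVH metrics, because D95% renormalisation
cancels a pure scale difference by construction, and the random rigid
shift is disabled in that cohort since the Dmin voxel extreme it perturbs
would otherwise drown the planted signal.

## Known limitations

* Spherical lesions and analytic dose mean that mask-resampling blur is
  the only source of PTV Dmin erosion; real plans have richer intra-PTV
  dose texture.
* The voxel-face shape convention overestimates surface area of smooth
  bodies (no marching-cubes mesh); shape features are internally
  consistent but not numerically interchangeable with mesh-based
  implementations.
* Gamma values above `exact_above` in fast mode are upper bounds, and all
  gamma values carry the `tol_gamma` certification tolerance.
* The radiobiological parameter file is non-clinical by design.
* The statistics layer reports raw p-values; a Benjamini–Hochberg column
  can be added trivially by the user but is not part of the mirrored
  presentation.
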