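---
title: "Imaging markers of CSF clearance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging markers of CSF clearance: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfclearance)
```

# Scope

`csfclearance` implements a multimodal pipeline for MRI markers of
cerebrospinal-fluid (CSF) based brain waste clearance in adult cohorts:

1. **White-matter perivascular spaces (WM-PVS)** — segmentation on the
   enhanced perivascular contrast (EPC) image by multiscale Frangi
   vesselness filtering with percentile thresholding, followed by per-region
   morphometry (count, volume, mean diameter, and count/volume fractions
   normalized by regional white-matter volume) over 56 bilateral
   Desikan-Killiany white-matter masks grouped into four lobes.
2. **DTI-ALPS** — the perivascular diffusivity index from tensor-element
   maps sampled in four fixed 5 mm spherical ROIs in template space.
3. **Volumetrics** — lateral-ventricle and choroid-plexus volumes
   normalized by estimated total intracranial volume (eTIV).
4. **Cohort inference** — permutation linear regression of each marker on
   group, mean-centered age and their interaction, with lobe-wise
   Bonferroni thresholds.

Upstream image processing (registration, tensor fitting, parcellation,
lesion segmentation) is out of scope: the package consumes its outputs.
Because raw cohort MRI cannot be redistributed, a synthetic-data module
generates phantoms, tensor fields, volumetric tables and cohorts with known
ground truth; every stage of the pipeline is validated against those.

# The PVS segmentation model

## EPC image

PVS are CSF-filled: dark on T1w, bright on T2w. The EPC image is the
voxel-wise ratio T1w/T2w inside the analysis mask (white matter minus any
lesion mask), which roughly squares the fluid contrast and makes PVS
strongly hypointense. The T2w denominator is clamped at a floor
(default `1e-6 ×` the in-mask median T2w value) so the ratio stays finite.

## Frangi vesselness

At each scale $\sigma$ the image is smoothed by a Gaussian and the Hessian
is computed from mm-scaled derivative-of-Gaussian kernels
($\gamma$-normalized with $\gamma = 1$, i.e. multiplied by $\sigma^2$, so
responses are comparable across scales). With eigenvalues ordered
$|\lambda_1| \le |\lambda_2| \le |\lambda_3|$ the tube ratios are
$R_A = |\lambda_2|/|\lambda_3|$, $R_B = |\lambda_1|/\sqrt{|\lambda_2
\lambda_3|}$ and $S = \sqrt{\sum_i \lambda_i^2}$, and

$$ V_\sigma = \left(1 - e^{-R_A^2/2\alpha^2}\right)
   e^{-R_B^2/2\beta^2} \left(1 - e^{-S^2/2c^2}\right), $$

set to zero for dark tubes unless $\lambda_2 > 0$ and $\lambda_3 > 0$.
The output is the maximum over scales. Parameter choices:

* $\alpha = \beta = 0.5$ — the conventional setting for perivascular work.
* $c$ = half the maximum in-mask Hessian norm $S$, computed **per scale**.
  The "half max norm" rule is ambiguous about pooling across scales;
  per-scale is the common reading and keeps every scale's third factor
  on a comparable footing.
* Scales: the default `sigmas = c(0.4, 0.6, 0.8)` mm targets structures
  1–3 voxels wide on 0.8 mm isotropic acquisitions. On the package's 1 mm
  phantoms the corresponding set `c(0.5, 0.75, 1.0)` mm is used. Scales are
  deliberately kept at or below the voxel scale: larger scales inflate the
  off-tube response halo, which degrades volume recovery (see below).
* Polarity: `dark` by default (tubes hypointense on EPC); `bright`
  reverses the eigenvalue sign condition.

Second-derivative kernels are corrected to zero sum, so constant images
produce exactly zero curvature; a scale whose in-mask $S$ is identically
zero contributes nothing and is flagged with a warning. Convolution uses
replicate (clamp-to-edge) boundaries.

## Percentile thresholding and why the phantom setting differs from 98

A voxel enters the PVS mask iff it lies in the analysis mask and its
vesselness strictly exceeds the given percentile of the *positive* in-mask
vesselness values. The percentile is applied through the empirical CDF, so
a tied block at the cut is kept together.

The default percentile is **98**: on real, noisy data nearly every
white-matter voxel has a small positive response, so the positives span the
whole mask and only the top tail is vessel-like. On noise-free phantoms the
situation inverts: the eigenvalue sign condition confines positive
responses to the embedded tubes plus a thin halo shell — measured at about
1.0–1.2× the embedded tube volume with the sub-voxel scale set — so the
phantom-recovery protocol uses **percentile 10**, trimming the halo while
keeping the tube interior. Both values are reported in the segmentation
metadata. This duality is a property of percentile thresholds: they select
a fixed fraction of the positive support, so the right percentile depends
on how much of the mask responds at all.

# PVS morphometry

Connected components of the binary PVS mask are extracted at
26-connectivity (default; 6 and 18 available). Each component is assigned
to the region holding the plurality of its voxels; components with more
than half their voxels outside every region are dropped (counted in a
message), and ties break to the lexicographically smallest region name.

Component shape uses the second central moment matrix of the voxel centers:
principal axis lengths are $4\sqrt{\text{eigenvalue}}$ (the matching
ellipsoid), and the **diameter** is the mean of the two minor lengths —
the average cross-sectional width of a tubular component. The mean diameter
per region averages over components (not voxels). Count fraction is
count per mm³ of regional white matter; volume fraction is dimensionless.

The feature table has one row per subject and `VF`/`CF`/`DM` columns per
region — 168 variables for the full 56-mask atlas — in a deterministic
order (lobe, canonical region order, hemisphere, metric).

# DTI-ALPS

Projection-fiber ROIs at $(\pm 25, -20, 28)$ mm and association-fiber ROIs
at $(\pm 39, -20, 28)$ mm, 5 mm diameter, membership by voxel-center
distance (no partial volumes; on a 1 mm grid each sphere holds 81 voxels).
Per hemisphere

$$ \mathrm{ALPS} = \frac{\mathrm{mean}(\overline{D_{xx}^{proj}},
   \overline{D_{xx}^{assoc}})}{\mathrm{mean}(\overline{D_{yy}^{proj}},
   \overline{D_{zz}^{assoc}})} $$

with each bar an ROI mean; hemispheres are computed first and then
averaged, rather than pooling the four ROIs. The index is invariant to
global rescaling of the tensor and equals 1 for isotropic fields.

# Volumetrics

Structure volumes are divided by eTIV. The reader accepts a flat TSV/CSV
dialect (`subject, structure, hemi, volume_mm3, etiv_mm3`) and a
FreeSurfer-style single-subject `aseg.stats` dialect, auto-detected by the
leading `#` header; missing structure rows or eTIV raise errors naming the
subject and field. Ratios at or above 1 are flagged as implausible but not
rejected.

# Cohort inference

Each marker is modeled as
`y ~ group + age_centered + group:age_centered` (group 0 = control,
1 = case; age centered at the sample mean). Inference is by permutation:

* **Scheme** — Freedman–Lane (default): for each term, fit the model
  without it, permute those residuals with a seeded generator, add them
  back to the reduced-model fits, refit the full model and collect the
  term's $|t|$. `ter_braak` and `raw_y` schemes are available for
  comparison. Freedman–Lane is the standard exchangeability-respecting
  choice for testing individual regression terms.
* **p-value** — two-sided add-one estimator $(1 + \#\{|t^\ast| \ge
  |t_{obs}|\})/(1 + B)$ with $B = 5000$ by default, never zero, with the
  tail comparison made tie-safe (a relative $10^{-12}$ slack) so exact
  ties such as the identity permutation under exhaustive enumeration are
  always counted.
* **Missing outcomes** — listwise per model.
* **Thresholds** — Bonferroni by family, where a family's divisor is its
  number of *masks*, not masks × metrics: 22/10/16/8 masks for the
  frontal/parietal/temporal/occipital lobes give 0.00227 / 0.00500 /
  0.00313 / 0.00625; paired volumes get 0.025 and the single ALPS index
  0.05. Significance uses the unrounded threshold; the displayed value is
  rounded to 3 significant figures, half away from zero.
* **Normality screen** — Shapiro–Wilk per outcome, advisory only (the
  permutation models run regardless); constant outcomes are flagged
  degenerate.
* Demographics use the classical equal-variance two-sample t-test and a
  Pearson chi-square without continuity correction on the 2×2 sex table.
  The equal-variance flavor is a documented convention; the chi-square
  choice reproduces published 2×2 results exactly.

Lobar summaries tally, per term, the uncorrected-significant rows by lobe
(as percentages of that term's significant rows, 1 decimal) and by
hemisphere.

# What the generators emulate — and what they do not

* **PVS phantoms** — randomly oriented tubes (default 2 per region, radius
  1–2 mm, length 8–16 mm, typical of MRI-visible PVS at this resolution)
  embedded in labeled box regions spanning both hemispheres and all four
  lobes on a 64³ voxel, 1 mm grid. Intensities: background 1.0 on both
  volumes; tube voxels 0.5 (T1-like) and 2.0 (T2-like), i.e. EPC contrast
  0.25 vs 1.0. Noise is additive Gaussian with sd = background/SNR (high-SNR
  Rician approximation; true Rician magnitudes are available). Ground-truth
  volume is the rasterized tube voxel volume — what is actually embedded in
  the image; the analytic $\pi r^2 L$ value is carried alongside and agrees
  within ±20% for radii at or above the voxel size. Tubes are placed wholly
  inside one region with at least a voxel of clearance between tubes so the
  per-region component count is well defined. Not modeled: bias fields,
  partial-volume decay, EPI distortion, motion — so passing phantom tests
  demonstrates correctness of the filtering/morphometry chain, not
  robustness to scanner physics.
* **Tensor fields** — prescribed Dxx/Dyy/Dzz means inside the four ALPS
  spheres over an isotropic background (0.8×10⁻³ mm²/s), optional Gaussian
  noise, and the analytically expected index. Defaults give an index of
  ≈1.39, in the healthy-adult range.
* **Cohorts** — 49 cases vs 61 controls, ages uniform on 30–73 years, one
  continuous outcome with configurable group/age/interaction effects and
  Gaussian residuals. Uniform ages slightly over-weight the extremes
  relative to a real cohort, which is conservative for calibration checks.
* **Volumetric tables** — positive-truncated normal draws around typical
  adult magnitudes (ventricles 15 mL, choroid plexus 0.6 mL, eTIV 1.5 L).

# Numerical choices and problem sizes

* Eigenvalues of the 3×3 Hessian fields use the vectorized trigonometric
  closed form with clamping of the acos argument; triples are sorted by
  absolute value with a three-element compare-swap network.
* Separable convolutions are implemented as banded matrix products with
  replicate edges; kernels are truncated at $4\sigma$.
* Connected components are computed on the voxel adjacency graph.
* Validation workloads were sized for a desktop run: segmentation recovery
  uses 20 phantoms at 64³ (about half a minute), and the type-I calibration
  uses 1000 null cohorts of n = 110 at B = 999 (under a minute), with
  B = 5000 reserved for real analyses. The exhaustive-permutation check
  enumerates all 720 permutations at n = 6.
* With all effects null, each term's empirical rejection rate at
  $\alpha = 0.05$ falls in [0.03, 0.07], and an interaction effect of
  0.02 outcome units per case-year (standardized effect ≈ 0.5 at n = 110)
  is recovered as the smallest interaction p among competing outcomes.

# Known limitations

* The Frangi scale set and threshold percentile are conventions; the
  sources validating them on clinical data are not reproducible here, so
  real-data use should treat the percentile as a required, reported
  configuration value.
* Whether the vesselness filter should run on EPC directly or on a
  normalized/inverted EPC is not settled; the filter here runs on EPC
  directly with dark polarity.
* Mean diameter is a component-level average; voxel-weighted definitions
  would weight long PVS more heavily.
* ALPS ROI placement is fixed in template space; per-subject manual
  adjustment after registration is not modeled.
* The permutation model covers exactly the three-term design; covariate
  adjustment beyond it (or mixed models) is out of scope.
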