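---
title: "Cerebellar morphometry and MRS biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebellar morphometry and MRS biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebmrs)
```

# Scope

Machado-Joseph disease (spinocerebellar ataxia type 3) produces cerebellar
atrophy, fourth-ventricle enlargement, white-matter loss and a
characteristic neurochemical profile (lower NAA, glutamate and taurine,
higher myo-inositol) that can be read out non-invasively with T2-weighted
MRI and single-voxel ¹H spectroscopy. `cerebmrs` implements the full
measurement chain for a two-species study design — a transgenic mouse model
imaged at high field with a surface coil, and a patient cohort with
age/sex covariates and clinical scores — together with seeded generators
for every input, so the chain can be exercised and validated end to end
without scanner data.

The pipeline has four computational stages:

1. **morphometry** — coil bias correction calibrated on a homogeneous
   phantom, bounded intensity normalization, Laplacian-of-Gaussian (LoG)
   contour segmentation of cerebellar WM/GM inside a supplied mask, and
   voxel-count volumetry;
2. **spectroscopy** — a linear-combination fit of a spectrum to a
   metabolite basis with Cramér–Rao lower bound (CRLB) reliability
   filtering, water/creatine referencing and the diagnostic ratios
   NAA/Ins and NAA/tCho;
3. **stats** — Welch tests, PCA with loading inspection, a from-scratch
   PERMANOVA, collinearity-screened multiple regression with a covariate
   retention rule and Bonferroni adjustment, and metabolite–behaviour
   regressions;
4. **synth** — the generators that define the study conditions.

# Synthetic data: what is emulated, what is not

## Digital phantom

`make_phantom()` builds a labeled volume on a coronal-acquisition grid
(default 128 × 128 voxels at 0.0781 mm in-plane, 24 slices of 0.5 mm). The
cerebellum is an ellipsoid (~49.7 mm³ at the default 3 mm radius, the
wild-type scale) whose short semi-axis lies in-plane and whose long axes
span slices: with 0.5 mm slices the through-plane direction carries the
coarsest quantization, and this orientation keeps the voxelization error of
ellipsoid volumes well under the 2% self-test tolerance. White matter is a
smooth four-lobed core occupying exactly `wm_fraction` (default 0.5) of
cerebellar voxels — an arborized shape that gives the LoG stage genuine
closed contours. The fourth ventricle is an ellipsoidal CSF compartment
placed caudal to the cerebellum whose voxel count is rank-selected to match
the requested volume to within half a voxel, because a structure only a few
slices thick cannot hit a 2% volume target by naive voxelization.

The coil gain is a separable exponential decay along the dorsoventral axis
(the surface-coil depth direction), normalized to mean 1;
`bias_strength` is its peak-to-trough ratio (default 1.5). Intensities are
`tissue_means[label] × gain + N(0, noise_sd)` with T2-like contrast
(CSF 9000 > GM 6000 > WM 3500 > background 800, arbitrary units). The
default `noise_sd = 100` (GM SNR ≈ 60, plausible for a 6-average RARE
acquisition at high field) is also what keeps a perfectly corrected
homogeneous phantom's coefficient of variation near 1.7%, inside the
pipeline's ≤2% flatness contract — at markedly higher noise no gain
correction could meet that contract, because the residual CV is the noise
CV itself.

Not emulated: k-space sampling, Rician noise (Gaussian is used; at these
SNRs the difference is negligible), partial-volume mixing (every voxel is
pure tissue — segmentation accuracy on phantoms is therefore an upper
bound on real-data accuracy), anatomy beyond ellipsoids and lobes.

## Spectra

`synth_basis()` builds 16 metabolite signatures as sums of Lorentzian lines
at approximate literature chemical shifts (shipped as a plain-text line
table; measured basis sets can be substituted through the same directory
format). `make_spectrum()` forms `Σ c_m · basis_m + polynomial baseline +
N(0, noise_sd)` on a descending 6.0–0.2 ppm axis of 1024 points. The
default `noise_sd = 0.2` was chosen so the CRLB profile looks like a real
mouse study: strong singlets (NAA, Cr, Ins, Tau) fit with sub-percent to
few-percent CRLB while the weak choline resonances sit in the high teens
and occasionally cross the 24% reliability threshold. The region above
4.5 ppm is left free of metabolite lines so a wide signal-free window
(4.5–6.0 ppm, ~265 points) is available for noise estimation.

Not emulated: FID-domain effects (eddy currents, frequency drift — spectra
enter already in the frequency domain), J-coupling multiplet structure,
macromolecule baselines beyond the broad Lorentzian humps and the
polynomial term.

## Cohorts

`mouse_cohort_spec()` reproduces the study layout (control/MJD × 2/4/16
months, cell sizes 14/14, 7/9, 7/6 with the recorded sex composition) with
per-group means and dispersions at the reported values for cerebellar,
WM and ventricle volumes and for the five key neurochemicals; the other
panel members get literature-scale means with null group effects (plus a
modest macromolecule/lipid increase). `NAA_NAAG` is generated as the exact
sum of its parts. Rotarod latencies depend linearly on NAA
(default slope 120 s/mM, residual SD 36 s), which at the disease-group
size of n = 22 reproduces the reported r² ≈ 0.35 regime.

`human_cohort_spec()` generates 18 controls / 16 patients with age and sex,
GM/WM/CSF volumes whose age slopes differ by group (GM −0.39 controls,
−0.72 patients; CSF slopes additionally sex-specific) and, for patients, a
jointly Gaussian clinical block (age of onset, disease duration, CAG
repeats, SARA). The default correlation targets put duration and CAG
above |r| = 0.7 with onset (−0.80 each) and with SARA (0.75 each) while
keeping onset–SARA at −0.35. Two structural choices matter for the
collinearity screen: (i) onset and SARA load on GM directly (−0.54 and
−0.50 mL/unit, the printed regression scale) while duration and CAG do
not; (ii) because duration correlates *negatively* with onset and
*positively* with SARA, the two drivers' contributions cancel in
duration's univariate correlation with GM — so the screen's AIC rule
faces a well-separated decision rather than a tie. GM residual noise
defaults to 5.8 mL, back-derived from the printed t-statistics at n = 16.

Generated correlations converge to the targets (±0.1 from n ≈ 200, a
generator self-test); marginal means obey the law of large numbers checks
in the test suite. Clamping (duration, SARA floored at 0.5; CAG rounded)
perturbs the correlations by far less than that tolerance.

# Morphometry

**Bias model.** The estimator follows the calibration-phantom idea
literally: the marginal mean intensity profile along each axis of the
homogeneous-phantom volume is fitted with a degree-4 polynomial, and the
gain is the separable product of the three curves, normalized to mean 1.
For a separable field — the geometry a single surface coil produces — the
marginals identify the field exactly up to scale; polynomial smoothing
suppresses noise without the boundary bias that kernel smoothing of the
full volume would introduce. Non-separable gains are flagged: if the
corrected calibration retains CV above `cv_tol` the estimator warns.

**Normalization.** Intensities map to grey levels 0–10,000 after excluding
1% of voxels as outliers, split 0.5% per tail (the split is configurable;
the total is the protocol value). Values at or beyond the tail quantiles
clamp to the range ends; the interior maps affinely.

**Segmentation.** The LoG response is computed with per-axis Gaussian
scales `sigma_mm / spacing` (full-3D by default; a per-slice mode matches
protocols that detected contours slice-wise) and a spacing-scaled discrete
Laplacian. Zero-crossings whose local jump exceeds `edge_threshold`
(default 1% of the masked response range) form the contour band; connected
components of the mask minus the band are the candidate regions; each
region is assigned WM or GM by its mean intensity against an Otsu split of
the masked intensities (WM darker on T2 contrast, polarity configurable),
and contour voxels are classified by their own intensity so the mask is
exactly partitioned. Two interactive steps of the original protocol are
replaced by batch equivalents: the whole-cerebellum outline is an input
mask, and the manual region-type selection is the intensity rule plus an
explicit per-region override argument. The LoG scale defaults to twice the
in-plane voxel size; with 0.5 mm slices this is sub-voxel through-plane,
which the function reports as a warning and proceeds — raise `log_sigma_mm`
or use `per_slice = TRUE` if that is not wanted. An image with no
above-threshold contour labels the whole mask GM (no-contrast contract).

**Volumetry.** Volumes are exact voxel counts times the voxel volume;
`fold_change()` reports max/min ratios with a direction flag, the form in
which the group contrasts (2.39× cerebellum, 1.85× ventricle, 1.33× WM)
are quoted.

# Spectroscopy

The fitter solves non-negative least squares over the basis plus an
unconstrained polynomial baseline (degree 2 default; each baseline column
enters as a ± pair under the NNLS solver). Basis pairs with |r| > 0.9995
are rejected up front as a conditioning error naming the pair. Noise is
estimated from the fit residuals in the signal-free window with the
standard n/(n−p) degrees-of-freedom correction; CRLB per metabolite is the
square root of the corresponding diagonal of σ̂²(AᵀA)⁻¹ for the
unconstrained design, quoted as a percentage of the fitted amount.
Amounts pinned at zero by the non-negativity constraint carry an
`at_bound` flag and an undefined CRLB, and are excluded — constraints are
never hidden by silent clipping. `apply_crlb_filter()` excludes strictly
above the threshold (exactly 24% is kept, the "higher than 24%" reading);
exclusion masks downstream use but preserves the fitted value.
Referencing (water constant / water area, or division by Cr + PCr) is
recorded in metadata and exactly invertible; ratios cancel it. NAA/tCho
uses tCho = PCh + GPC; a ratio with any excluded ingredient propagates a
missing value with the reason, never a zero.

# Statistics

- **Welch test**: `stats::t.test` with Satterthwaite df, wrapped to a
  fixed return shape (the degenerate identical-sample case returns t = 0,
  p = 1 rather than erroring).
- **PCA**: `stats::prcomp` (correlation form by default, since the panel
  mixes units; covariance form is a flag), with percent variance explained
  and the top-|loading| table per leading component.
- **PERMANOVA**: implemented from the distance-partition definition —
  `SS_total = Σ_{i<j} d²_ij / n`, within-group analogue per group,
  pseudo-F from the between/within mean squares — with seeded label
  permutations and the observed statistic included in the reference set,
  so the smallest attainable p is 1/(B+1). On univariate Euclidean input
  it reduces exactly to the classical one-way ANOVA F, which the tests
  assert to 1e-10 alongside an independent-implementation cross-check.
  Permutations default to 9999.
- **Collinearity screen**: for every candidate pair with |r| > 0.7, keep
  the member whose univariate Gaussian regression on the outcome has the
  lower AIC, computed as n·log(RSS/n) + 2k (stated explicitly because AIC
  conventions differ by constants); ties break by lower p, then
  alphabetically; pairs resolve in deterministic alphabetical order; AIC/p
  disagreements are resolved by AIC and flagged in the drop log.
- **Covariate retention**: the group × age × sex model keeps a covariate
  only when the joint F-test of *all* terms involving it is significant at
  α = 0.05, removing bundles backward (group is never removed). Testing
  the covariate as a bundle, rather than term-by-term, is what makes the
  rule specific: under a null sex effect the false-retention rate is the
  single-test 5% rather than the ~20% that per-term sequential testing
  accumulates across four sex terms. Per-stratum age slopes (β ± SE, t, p)
  are derived from the fitted coefficients with delta-method contrasts.
- **Bonferroni**: p × m clipped at 1, m defaulting to the number of terms
  supplied.

# Numerical choices and degenerate inputs

Filtering uses row-normalized Gaussian operators (boundary rows
renormalize over in-grid support) and Neumann second differences, applied
axis-by-axis as dense operator matrices — exact, fast at these grid sizes,
and free of FFT wrap-around. Otsu thresholds use 256 bins. Connected
components use 6-connectivity (per-slice 4-connectivity in per-slice mode,
so in-plane contours cannot leak across slices). Constant images are
rejected by normalization (undefined scale) and by the PERMANOVA distance
check; empty masks, axis mismatches, non-positive calibrations,
rank-deficient designs and out-of-range p-values raise typed errors named
in the function contracts. All generators draw from an explicit seed via
`withr::with_seed`, leaving global RNG state untouched; every pipeline
stage is a pure function of (inputs, config, seed).

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen as the
smallest sizes at which each property is statistically meaningful:
10 default-resolution phantoms for segmentation recovery; 100 spectral
replicates × 16 metabolites for CRLB calibration; 500 null datasets
(99 permutations each) for permutation-p uniformity and 2000 replicates
for the Welch level; recovery regressions at n = 200 with reduced noise
(the regime in which a 10% recovery band is ~3 standard errors); the
collinearity screen at n = 100 per group over 100 seeds — at the study's
own n = 16 the sampling noise of correlations around the 0.7 threshold
makes any fixed screening outcome unreliable, which is a property of the
procedure at that sample size, not of this implementation.

# Limitations

Phantoms are pure-tissue and geometric; Dice scores near 1 on them verify
the contour machinery, not clinical-grade segmentation. The shipped basis
is synthetic (Lorentzian singlet approximations) — quantification on real
spectra requires a measured basis via `read_basis_dir()`. The CRLB here is
exact for the linear model; a nonlinear fitter's reported bounds also
absorb lineshape and shift uncertainty. Human volumetry enters as a
cohort table: no human image segmentation is performed. The fitter has no
macromolecule model beyond the broad basis humps and the polynomial
baseline, and no absolute-unit calibration against tissue water fractions.
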