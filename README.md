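# cerebmrs

Cerebellar morphometry and ¹H-MRS biomarkers for Machado-Joseph disease
(spinocerebellar ataxia type 3, SCA3) studies in mouse models and patients.

MJD causes cerebellar atrophy, fourth-ventricle enlargement, white-matter
loss and a characteristic neurochemical shift — lower N-acetylaspartate
(NAA), glutamate and taurine, higher myo-inositol — all measurable in vivo
with T2-weighted MRI and single-voxel proton spectroscopy. `cerebmrs`
implements the full measurement chain for such studies, plus seeded
generators for every input, so the pipeline runs and validates end to end
without scanner data. It is aimed at preclinical imaging groups who need a
reproducible, auditable readout for therapy trials in ataxia models.

## What it computes

**Morphometry.** A coil bias field is estimated from a homogeneous
calibration phantom via per-axis intensity curves and divided out; the
image is normalized to grey levels 0–10,000 after 1% outlier exclusion;
cerebellar white and grey matter are separated inside a supplied mask by
Laplacian-of-Gaussian contour detection — zero-crossings of
∇²(G_σ ∗ I) above an edge threshold bound candidate regions, which an
intensity rule (or explicit override) assigns to WM/GM; volumes are voxel
counts × voxel volume, and group contrasts are reported as fold changes
(e.g. 49.62/20.73 → 2.39-fold cerebellar decrease).

**Spectroscopy.** A spectrum S(ppm) is fitted as a non-negative linear
combination Σ c_m B_m(ppm) + polynomial baseline over a metabolite basis;
per-metabolite reliability is the Cramér–Rao lower bound
CRLB_m = √[σ̂²(AᵀA)⁻¹]_mm / c_m (noise estimated in a signal-free window),
and metabolites with CRLB > 24% are excluded from analysis. Results can be
referenced to water or total creatine; the marker ratios NAA/Ins and
NAA/tCho (tCho = PCh + GPC) are derived with explicit missingness.

**Statistics.** Welch t-tests; PCA with variance-explained and loading
reports; PERMANOVA implemented from the distance-partition definition
(pseudo-F = [SS_B/(a−1)]/[SS_W/(n−a)] with seeded label permutations);
collinearity screening (|r| > 0.7 resolved by univariate AIC, then p);
group × age × sex regressions with a joint-F covariate retention rule and
Bonferroni adjustment; metabolite–behaviour (rotarod) regressions.

**Synthetic data.** Labeled digital phantoms with an arborized WM core,
ventricle compartment, separable coil gain and Gaussian noise; Lorentzian
metabolite bases and spectra with known ground truth; mouse and human
cohort tables with the study's group means, age structure, rotarod
dependence on NAA, and a correlated clinical block (onset, disease
duration, CAG repeats, SARA).

## Worked example

```r
library(cerebmrs)

# synthesize an acquisition and its calibration phantom
spec <- phantom_spec(seed = 42)
phantom <- make_phantom(spec)
calibration <- make_homogeneous_phantom(spec)

# bias-correct, normalize, segment, measure
bias <- estimate_bias(calibration)
img <- normalize_intensity(correct_bias(phantom$image, bias))
mask <- array(phantom$labels$labels %in% c(1L, 2L),
              dim = dim(phantom$labels$labels))
seg <- segment_wm_gm(img, mask)
measure_volumes(seg)
#>       tissue voxel_count  volume_mm3
#> 1 background      376992  1149.75209
#> 2         GM        8113    24.74307
#> 3         WM        8111    24.73697
#> 4 cerebellum       16224    49.48004

dice_coefficient(seg$labels == 2L, phantom$labels$labels == 2L)
#> [1] 0.9999384

fold_change(49.62, 20.73)   # printed wild-type vs MJD cerebellar means
#> $ratio      2.393632
#> $direction  "decrease"

# fit a disease-like spectrum and derive the marker ratios
basis <- synth_basis()
sp <- make_spectrum(basis, group_mean_concentrations()$MJD,
                    baseline_coeffs = c(2, 0.5), seed = 7)
fit <- apply_crlb_filter(fit_spectrum(sp, basis), 24)
head(fit$table, 5)
#>   metabolite concentration crlb_percent included at_bound
#> 1        NAA     0.7472301    4.4193475     TRUE    FALSE
#> 2       NAAG     0.2527889   15.3580920     TRUE    FALSE
#> 3         Cr     3.9005763    1.0574226     TRUE    FALSE
#> 4        PCr     4.2967988    0.9102219     TRUE    FALSE
#> 5        Glu     4.2288510    1.1141309     TRUE    FALSE
compute_ratios(fit)
#>      ratio     value reason
#> 1  NAA/Ins 0.1077082   <NA>
#> 2 NAA/tCho 0.8906017   <NA>

# statistics on a synthetic mouse cohort
cohort <- make_cohort(mouse_cohort_spec(seed = 1))
permanova(cohort, metabolite_panel(), "group",
          n_permutations = 999, seed = 1)
#> <permanova_result> pseudo-F = 12.7678 (df 1, 55), p = 0.001 (999 permutations)
```

The fitted NAA (0.747) recovers the generated disease-group mean (0.71)
within its CRLB; the NAA/Ins ratio is roughly half the control-group
value, the direction the disease model predicts; the metabolite panel
separates the groups decisively under PERMANOVA.

A full run (`run_all(run_config(seed = 1), "out/")`) writes the
paper-shaped tables — `volumes.tsv`, `fold_changes.tsv`,
`metabolites.tsv`, `ratios.tsv`, `stats/*.tsv` — plus a `manifest.json`
with config echo, stage timings and file checksums. A thin CLI lives at
`inst/cli/cerebmrs-pipeline.R`:

```sh
Rscript inst/cli/cerebmrs-pipeline.R --seed 1 --out run1
```

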