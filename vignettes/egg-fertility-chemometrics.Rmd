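---
title: "Methods: Vis-SWNIR transmission chemometrics for day-0 egg fertility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Vis-SWNIR transmission chemometrics for day-0 egg fertility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ovispec` implements a complete chemometric pipeline for discriminating
fertile from infertile unincubated chicken eggs using transmission
hyperspectral images in the 500–950 nm window. This vignette is the
package's account of the science: the model behind each stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, the numerical choices, and the known limits of what the
test suite demonstrates.

## 1. The measurement model

A line-scan imager transilluminates a vertically held egg and records a
hypercube of `rows × cols` pixels by `bands` wavelengths at exposure time
`e_s` (100 ms by default). Two calibration acquisitions accompany a
campaign: a *dark* frame (lamp off, cap on, exposure `e_s`) measuring the
detector's dark signal, and a *reference* frame (unattenuated lamp,
exposure `e_r` ≪ `e_s`, default 1 ms, short enough not to saturate).

Because the embryonic disc is invisible at day 0, the region of interest is
the whole egg. The mean in-egg spectrum `T_s` is converted to relative
transmittance in percent with the exposure-corrected ratio

$$T_{rel} \;=\; \frac{T_s/e_s - T_d/e_s}{T_r/e_r - T_d/e_s} \times 100,$$

where `T_d` and `T_r` are the full-frame mean dark and reference spectra.
Note that the dark term is divided by the *sample* exposure in both
numerator and denominator. Dividing the denominator's dark term by `e_r`
instead may look more natural if one thinks of dark current as accumulating
in the reference frame over its own exposure; that variant is available as
`convention = "per_frame"` in `relative_transmittance()`, but the default
keeps the first form, which in the package's own intensity model
(`intensity = (flux + dark_rate) × exposure`) is exactly invertible: with
zero noise the extracted `T_rel` reproduces the generating transmission
curve times a constant path-length factor to machine precision, a property
the test suite asserts.

`T_rel` is invariant to any global detector gain (the test suite checks
this too), which is the point of the ratio: it removes the optical system's
signature.

### Segmentation

The egg must be separated from the background on the band with the best
contrast, nearest 630 nm. The recipe in `segment_egg()` is classical: Sobel
gradient magnitude, threshold at the gradient's Otsu level, morphological
closing, hole filling, largest connected component. One refinement is the
package's own: a transilluminated egg has no sharp rim — the optical path
length through an ellipsoid falls to zero at the silhouette edge — so the
filled gradient band straddles the true boundary and by itself caps the
intersection-over-union with the true region near 0.93. The final mask is
therefore re-thresholded on intensity at *background mean + 3 background
standard deviations*, with background statistics estimated outside the
dilated edge region. On phantoms this yields IoU 1.0 without noise and
≥ 0.99 at the default noise level.

### Band binning

Raw acquisitions oversample the spectral axis (e.g. 1279 native bands);
`bin_bands()` averages contiguous blocks down to the working grid (256
bands over 500–950 nm, ~1.76 nm/band). Blocks are as equal as possible,
remainder bands joining the trailing blocks, and the output wavelength is
the mean of each block's members. Binning commutes with ROI averaging (mean
of means with equal weights), asserted to 1e-9.

## 2. Pretreatments

Seven row-local pretreatments mirror standard chemometric practice
(`pretreat()`): raw, unit-vector normalization, SNV, MSC, linear baseline
correction, and Savitzky–Golay first and second derivatives. Choices the
literature leaves open were fixed as follows:

* **SG window/order**: 11 points, polynomial order 2 — common defaults at
  ~1.8 nm/band; derivatives are per band step. Exposed as arguments.
* **"Normalization"**: division by the spectrum's Euclidean norm (the
  standard vector normalization); alternatives are trivial to add but not
  defaulted.
* **"Baseline correction"**: subtraction of the straight line through the
  spectrum's first and last points — the simplest reproducible reading of
  baseline removal.
* **MSC reference**: the mean calibration spectrum, learned from
  calibration rows only and reused on test rows. The test suite perturbs
  non-calibration rows and asserts the learned correction is unchanged (no
  test-set leakage).

**Outlier screening** (`hotelling_outliers()`) computes Hotelling T² over
the leading principal components (default: components covering 95% of
variance, capped at 10) and flags samples beyond the F-based 95% limit with
the usual `k(n−1)(n+1)/(n(n−k))` scaling for in-sample scores. On
homogeneous Gaussian data the flag rate sits at ~5% as it should. Screening
is applied to the *calibration* subset after the split, so the independent
test set is never touched; whether the original study screened before or
after its split is unreported, and screening after keeps the test set
honest.

**Split** (`split_calibration_test()`): random 80/20, stratified by class
(per-class counts within one sample of the target fraction), seeded. A
131 + 96 campaign yields the 26 fertile + 19 infertile test composition
used throughout the worked examples.

## 3. SIMCA and discrimination power

`simca_fit()` builds one PCA sub-model per class: class mean, leading
`n_pcs` loadings, per-variable residual variances
`s²_j = Σᵢ e²_ij / (n − k − 1)` and pooled residual variance
`s₀² = ΣΣ e²_ij / ((n − k − 1)(p − k))` (the standard degrees-of-freedom
correction; a naive mean-squares variant is selectable with
`df = "naive"`). A new sample's reduced distance to a class is
`d = s_sample/s₀` with `s²_sample = Σⱼ e²_j / (p − k)`; membership is
accepted when `d²` is below the 95% F quantile, and the forced single
assignment — what fills confusion matrices — is the smallest `d`, exact
ties going to the first class in sorted label order and flagged ambiguous.

Per-class component counts, when not pinned, are chosen by 5-fold
cross-validated misclassification on the calibration set with a per-class
coordinate search bounded at 10 components — the "trial and error on
calibration" route at a tenth of the cost of leave-one-out, with folds
drawn from the fit's seed.

The **discrimination power** of variable `j` between classes A and B is

$$DP_j = \sqrt{\frac{s_j^2(A\!\to\!B) + s_j^2(B\!\to\!A)}
                    {s_j^2(A\!\to\!A) + s_j^2(B\!\to\!B)}},$$

with all four terms computed under one degrees-of-freedom convention, so
identical classes give exactly DP = 1 and the profile is symmetric in class
order. The one-directional variant (project A's rows onto B's model only)
is exposed via `direction = "one_way"` since published profiles do not
always say which form they use. Wavelengths with DP > 3 are conventionally
useful; `select_regions()` turns maximal runs of such bands into contiguous
wavebands.

**Which pretreatment feeds the DP profile?** The pipeline computes DP on
MSC-corrected spectra. First-derivative spectra — attractive because they
give the best whole-spectrum classifiers — smear the sharp flanks of narrow
discriminative bands across the SG window (±5 bands ≈ ±9 nm), spilling
apparent discrimination power outside the true intervals. MSC removes
per-egg multiplicative/additive scatter exactly and leaves the
class-discriminative structure in place, localizing DP to the planted
bands; under the default generator, region recovery is 10/10 seeds with
zero false bands.

## 4. LDA, QDA and the neural network

With ~200 calibration rows and 256 collinear wavelengths, raw-spectrum
covariance matrices are singular, so `da_fit()` fits LDA/QDA in a PCA score
space retaining components that explain 99% of calibration variance, capped
at 40 and at what the smallest class supports; priors are the empirical
class frequencies (matching the imbalanced 131/96 design). The Gaussian
model itself is `MASS::lda`/`MASS::qda`; the package's tests verify QDA
posteriors against hand-computed Gaussian density arithmetic.

`mlp_fit()` trains the era-appropriate architecture: one input layer, one
hidden layer (logistic units), two softmax output nodes, cross-entropy
loss, back-propagation (`nnet`), inputs standardized with
calibration-derived statistics only. Published work of this kind rarely
reports epochs, learning rates, or stopping rules; the package regularizes
with weight decay (default 1e-3, 500 epochs max) instead of
validation-based early stopping, because decay is native to the optimizer,
makes runs exactly reproducible from one seed, and serves the same
overfitting-control purpose. `topology_search()` reproduces the
trial-and-error topology scan: for each hidden-layer size, `repeats = 3`
networks are trained with derived seeds (`seed × 1000 + r`) on an internal
75/25 split of the calibration set — the external test set stays untouched
— and mean validation accuracy is plotted (`autoplot()`); ties break toward
the smaller topology.

`sensitivity_analysis()` scores input importance as the ratio of network
error with that input replaced by its calibration mean to the error on
intact data (the mean-substitution convention of classic neural-network
software; a permutation variant is included). A constant input scores
exactly 1; redundant copies of an informative input share, and therefore
dilute, its score — both behaviours are asserted in the tests.

## 5. Reduced feature sets

`region_features()` restricts raw spectra to the selected wavebands.
`spectral_differences()` forms `T(λ₁) − T(λ₂)` for every unordered pair of
selected wavelengths (default scope: all pairs across the union of regions,
with `within_region` as an option) — the standard stand-in for a first
derivative when the retained wavelengths are discontinuous. On smooth
noiseless spectra, adjacent-band differences correlate > 0.9 with the SG
first derivative, which is the rationale for using them.

## 6. The synthetic generator: what it emulates, and what it does not

No day-0 egg hyperspectral dataset is public, so `synth_config()` +
`generate_dataset()`/`simulate_spectra()` define the study conditions the
package is exercised under:

| parameter | default | emulates |
|---|---|---|
| `n_fertile`, `n_infertile` | 131, 96 | the campaign's class sizes |
| `rows × cols × n_bands` | 64 × 64 × 256 | desk-scale geometry (400 × 400 available via config) |
| `wavelength_range` | 500–950 nm | the usable spectral window |
| `absorption_centers` | 580, 634, 665, 730, 770, 830, 930 nm | carotenoid and O–H/C–H overtone transmission valleys |
| `absorption_depths`, `absorption_widths` | 0.30, 12 nm | valley geometry, shared by both classes |
| `fertile_transmission_gain` | 1.04 | fertile eggs transmit more overall |
| `class_effect_bands` | 673–675, 798–800, 813–840, 865–873 nm | the narrow NIR wavebands where fertility expresses |
| `class_effect_size`, `class_effect_sd` | 0.05, 0.03 | mean and per-egg spread of the expressed extra absorption |
| `scatter_slope_sd`, `scatter_offset_sd` | 0.05, 0.01 | per-egg multiplicative/additive scatter |
| `shape_poly_sd` | 0.01 | smooth per-egg spectral shape variability (degree-3 polynomial) |
| `band_scatter_sd` | 0.01 | per-egg band-scale spectral jitter |
| `noise_sd` | 25 intensity units | additive detector noise |
| `exposure_sample`, `exposure_reference` | 100, 1 ms | the two acquisition exposures |
| `egg_axes`, `background_level`, `dark_current` | (24, 18) px, 30, 0.2/ms | phantom geometry and detector floor |

Each cube is *lamp spectrum × per-egg transmission curve × per-pixel
ellipsoid chord-length factor* inside the elliptical egg, background
outside, plus dark current and Gaussian noise. The lamp is Planck radiance
at 3250 K (tungsten-halogen). The fertility effect is a raised-cosine lobe
inside each effect interval — absorption features are peaked, not
rectangular — normalized so each interval's best-covered band expresses the
full effect; its per-egg expressed strength is `max(0, N(0.05, 0.03))`, so
weakly expressing fertile eggs genuinely overlap the infertile class and
classification is imperfect, as it is in real campaigns. No published
quantitative effect size exists for any of these magnitudes; they were
chosen once as a realistic regime in which default-condition classifiers
score in the mid-80s to low-90s percent and the discrimination-power
profile localizes to the planted bands, and they are not revisited.

The generator deliberately does **not** model: embryo/blastoderm
morphology or any spatial class signal (the method's premise is that day-0
information is spectral), Poisson photon statistics (additive Gaussian
noise is sufficient to exercise smoothing and SNR and is simpler to seed),
eggshell pigment chemistry (white-shell eggs only), detector nonlinearity,
or wavelength miscalibration. Consequently, passing tests demonstrate the
*pipeline* is correct and well calibrated under known conditions — they do
not certify real-egg classification accuracy. One visible divergence:
with purely flat per-egg scatter, *raw* selected-region and
spectral-difference features retain little class signal (near the published
linear-classifier results on those feature sets, but below the published
ANN results), whereas scatter-corrected region features classify well; on
real eggs the reduced features evidently carry more egg-specific structure
than the generator plants.

## 7. Numerical conventions and degenerate inputs

* Band indexing is 1-based (R); wavelength grids are band centers; nearest
  band selection breaks ties toward the lower index.
* Wavelength column names round-trip through `%.12g` formatting, so grids
  survive table ↔ matrix conversion exactly; region membership tests use a
  1e-6 nm tolerance.
* Metrics are exact ratios at full precision; display rounding is half-up
  to 2 decimals (`format_metrics()`); a metric with a zero denominator is
  `NA`, never 0.
* Degenerate inputs fail loudly with the offending sample or band named:
  zero-variance rows under SNV, zero-norm rows under normalization, MSC
  slopes below 1e-12, non-positive reference-corrected denominators, empty
  masks, empty segmentations, a class too small to split or model.
* Distance/posterior ties are broken deterministically (first class in
  sorted label order) and flagged `ambiguous`.
* Infinite DP (zero within-class residual variance at a band) is reported
  as `Inf` with a warning and treated as above-threshold in region
  selection.

## 8. Problem sizes

The test suite and acceptance script run the full spatial/spectral
geometry (64 × 64 × 256) with egg counts chosen per purpose: the complete
227-egg campaign for the acceptance run, 105 eggs for classifier-regime
checks, 70–80 eggs per seed for the ten-seed discrimination-power recovery
study, and 2–6 egg micro-campaigns for closed-form identities. These sizes
are the package's chosen study scales; the `rows = cols = 400`
configuration reproduces the full acquisition geometry when wanted.

## 9. Known limitations

* Two-class SIMCA only; Coomans-style membership values are computed but
  no dedicated membership plot is provided.
* The experiment grid fixes the reduced feature sets to raw spectra (the
  premise being that derivatives are ill-defined across discontinuous
  wavebands), so pretreatment × reduced-features cells are not enumerated.
* `read_envi()`/`write_envi()` support exactly the double-precision BSQ
  layout the package writes — they are campaign persistence, not a general
  ENVI implementation.
* The ANN stack is deliberately era-faithful (one hidden layer, BP);
  no modern architectures, which is a scope choice, not an oversight.
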