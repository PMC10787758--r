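# ovispec

Chemometric analysis of Vis-SWNIR (500–950 nm) transmission hyperspectral
images for detecting infertile chicken eggs **before incubation** (day 0).
At day 0 the blastoderm is far too small to image spatially, so the signal
is purely spectral: an egg's mean relative-transmittance spectrum, extracted
over the segmented egg region, carries faint compositional differences
between fertile and infertile eggs concentrated in a few narrow
end-of-visible/NIR wavebands. `ovispec` implements the full pipeline —
hypercube segmentation and spectrum extraction, spectral pretreatments,
outlier screening, four classifier families, discrimination-power waveband
selection, and spectral-difference features — together with a synthetic
hypercube generator so everything is testable end to end without any
proprietary data.

The package is tidyverse-native: spectrum tables, selected regions, and
metric reports are tibbles that flow through dplyr verbs; fitted models have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## The methods at the core

**Relative transmittance.** Raw mean intensities are converted to percent
transmittance against dark and reference acquisitions captured at exposure
times `e_s` and `e_r`:

    T_rel = (T_s/e_s − T_d/e_s) / (T_r/e_r − T_d/e_s) × 100

**SIMCA.** Each class gets its own PCA sub-model; a sample's membership is
judged by its reduced residual distance `d = s_sample/s0` with an F-test.
The per-wavelength **discrimination power** between two classes A and B is
the cross- over within-class residual-variance ratio

    DP_j = sqrt( (s²_j(A→B) + s²_j(B→A)) / (s²_j(A→A) + s²_j(B→B)) )

where `s²_j(X→M)` is class X's mean squared residual at wavelength `j`
under model M. DP ≈ 1 means uninformative; maximal runs of bands with
DP > 3 become the *effective wavebands*, which feed two reduced feature
sets: the raw spectra restricted to those bands, and all-pairs spectral
differences `T(λ₁) − T(λ₂)`.

**Classifiers.** SIMCA (authored here), LDA/QDA in PCA score space
(`MASS`), and a single-hidden-layer feed-forward network (`nnet`) with
topology search over the hidden-layer size and mean-substitution
sensitivity analysis.

**Evaluation.** Confusion matrices with *fertile* as the positive class and
Sen/Spe/Precis/Acc in percent.

## Worked example

Simulate a labelled campaign, extract spectra through the imaging chain,
screen outliers, correct scatter, fit SIMCA, select wavebands, and score
the held-out test set:

```r
library(ovispec)
library(dplyr)

cfg     <- synth_config(n_fertile = 60, n_infertile = 45, seed = 7)
spectra <- simulate_spectra(cfg)          # segment + extract + Eq. above
split   <- split_calibration_test(spectra, test_fraction = 0.2, seed = 1)
cal     <- hotelling_outliers(split$calibration)$kept
cal_msc <- pretreat(cal, "msc")

fit <- simca_fit(cal_msc, seed = 1)
tidy(fit)
#> # A tibble: 2 × 4
#>   class         n n_pcs    s0
#>   <chr>     <int> <int> <dbl>
#> 1 fertile      47     8 0.216
#> 2 infertile    35     2 0.230

dp      <- discrimination_power(fit, cal_msc)
regions <- select_regions(dp, threshold = 3)
select(regions, region_id, start_nm, end_nm, n_bands)
#> # A tibble: 4 × 4
#>   region_id start_nm end_nm n_bands
#>   <chr>        <dbl>  <dbl>   <int>
#> 1 R1            673.   673.       1
#> 2 R2            800.   800.       1
#> 3 R3            824.   830.       4
#> 4 R4            868.   870.       2

test_msc <- pretreat(split$test, "msc",
                     msc_reference = colMeans(spectra_matrix(cal)))
pred <- predict(fit, test_msc)
metrics(confusion_matrix(split$test$class, pred$.pred_class))
#> # A tibble: 1 × 8
#>      TP    FN    FP    TN   sen   spe precis   acc
#>   <int> <int> <int> <int> <dbl> <dbl>  <dbl> <dbl>
#> 1    11     1     0     9  91.7   100    100  95.2
```

The four selected regions recover exactly the narrow wavebands the
generator plants the fertility effect in (673–675, ~799, 813–840,
865–873 nm); the test metrics read as: 11 of 12 fertile eggs and all 9
infertile eggs correctly classified, accuracy 95.2%. `autoplot(dp)` draws
the discrimination-power profile with the selected regions shaded, and
`run_experiment_grid()` orchestrates the full pretreatment × classifier ×
feature-set design in one call.

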