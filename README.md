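# petrad — robust PET radiomics survival modeling

`petrad` is an R implementation of a robustness-screened PET radiomics
workflow for survival prognosis in advanced lung cancer, together with a
synthetic-data generator that makes every stage testable without access to
patient data.

The scientific problem: radiomics features extracted from FDG-PET lesions
are notoriously sensitive to how the lesion was delineated and to the
extraction settings (gray-level bin width, voxel resampling). A model built
on fragile features will not transfer. The workflow implemented here
addresses that in four stages:

1. **Segmentation perturbation.** Each lesion gets five contour variants:
   fixed-threshold contours at 35 %, 40 % and 45 % of SUVmax, plus two
   volume-perception surrogates (CT-window and PET-display perception).
2. **Extraction perturbation.** Features are extracted under six parameter
   sets — bin widths {5, 25, 75} × {original resolution, 1 mm isotropic
   resampling} — over the original image, Laplacian-of-Gaussian filtered
   images and the eight subbands of a one-level 3D Haar wavelet transform
   (first-order, 3D shape, GLCM, GLRLM, GLSZM, NGTDM and GLDM families).
3. **Stability screening.** Each feature's agreement across perturbations
   is measured with the intraclass correlation ICC(2,1) (two-way random
   effects, absolute agreement, single measurement),

       ICC(2,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E)),

   and features with ICC > 0.75 under *both* perturbation families are
   kept.
4. **Modeling.** A nested cross-validated elastic-net Cox workflow
   (outer 5-fold; repeated inner 5-fold grid search over the penalty
   mixing, path depth and strength) selects the 7 most frequently retained
   features; the winning 7-feature model stratifies held-out patients at
   the mean risk score (Kaplan–Meier curves, logrank test, Harrell's C),
   and a from-scratch balanced random forest classifies 1-year survival on
   the same 7 features (grid-searched, AUC/confusion reporting).

Because no public dataset accompanies the original cohort (99 stage IVB
NSCLC patients, 79/20 train/test), the `synthetic_data` module simulates
PET-like spherical lesions with a controllable multiplicative
Gaussian-random-field texture and plants known Cox coefficients on the
texture parameters, so that feature-selection recovery and null
calibration are verifiable properties, not anecdotes.

## Worked example

```r
library(petrad)

spec <- phantom_spec(grid_shape = c(20L, 20L, 12L), spacing_mm = c(3, 3, 3),
                     lesion_radius_mm = 12, heterogeneity_sd = 0.3, seed = 7L)
ph <- generate_phantom(spec)
print(ph$volume)
#> <pr_volume> 20 x 20 x 12 voxels, spacing 3 x 3 x 3 mm, range [0.2138, 10.48]

lesion_suvmax(ph$volume, ph$true_mask)
#> [1] 10.48185

ms <- make_mask_set(ph$volume, ph$true_mask, true_mask = ph$true_mask)
vapply(ms$variants, function(m) sum(m$values), 0)
#>  ct_perception pet_perception          suv35          suv40          suv45
#>            280            390            160            142            117

fv <- extract_all(ph$volume, ms$variants$suv40,
                  extraction_config(bin_width = 0.5, wavelet = FALSE,
                                    log_sigmas_mm = numeric(0)))
round(fv[c("original_firstorder_Mean", "original_glcm_Contrast",
           "original_shape_Sphericity")], 4)
#>  original_firstorder_Mean    original_glcm_Contrast original_shape_Sphericity
#>                    6.1684                   14.4024                    0.9493

icc21(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2))$icc
#> [1] 0.8888889
```

The numbers mean: the noisy phantom's realized SUVmax (10.48) drives the
threshold contours, whose voxel counts shrink monotonically as the
threshold rises (160 → 142 → 117) while the perception surrogates bracket
them; the suv40 VOI yields 107 features under this reduced configuration;
and the 3×2 worked ICC layout decomposes into MS_R = 8, MS_C = 1.5,
MS_E = 0, giving ICC = 8/9.

The full pipeline (simulate → segment → extract → screen → survive →
classify) runs from one seeded configuration and writes a JSON + Markdown
report with ICC summaries, per-variant concordance, logrank χ²/p and
classification metrics:

```r
report <- run_pipeline(pipeline_config(cohort = cohort_spec(n_subjects = 20L,
                                                            seed = 1L),
                                       seed = 1L),
                       out_dir = "pipeline_out")
```

A command-line front end with `simulate | segment | extract | screen | run`
subcommands is installed at `inst/cli/petrad`.

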