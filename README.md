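# tumorscan

Recognition of tumors in 2-D brain MRI slices with a classical,
fully inspectable pipeline: percentile **contrast stretching**,
edge-preserving **anisotropic diffusion** denoising with an
iteration-error stopping rule, **first-order + GLCM texture features**,
brightness-threshold + morphological **tumor localization**, standard
**image-quality metrics** (SSIM, MSE, PSNR, Dice), and a
**Gaussian-kernel SVM** that labels each slice normal or abnormal.

The package is aimed at medical-image-analysis practitioners who want a
reproducible, dependency-light baseline for slice-level tumor screening
— every stage is a plain R function over a numeric intensity matrix in
`[0, 1]`, with the numerics tested against independent brute-force
oracles. Because clinical MRI cannot ship with a package, a seeded
**synthetic brain-phantom generator** with ground-truth masks drives
all tests and the reproduction script; real PNG/JPEG/TIFF slices go
through the same `load_image()` entry point.

## The method in brief

Denoising evolves the image by the explicit four-neighbor diffusion
scheme

&nbsp;&nbsp;&nbsp;&nbsp;I⁽ᵗ⁺¹⁾ᵢⱼ = Iᵗᵢⱼ + Δt · Σ_{k∈N₄} c_k (Iᵗ_k − Iᵗᵢⱼ),&nbsp;&nbsp;&nbsp;&nbsp;c = g(|∇I|), g(s) = exp(−(s/κ)²) or 1/(1+(s/κ)²),

with Δt = 1/4 (the stability bound) and stops when the relative
iteration error IE = ‖Iₙ − Iₙ₋₁‖_F / ‖Iₙ‖_F falls to a tolerance —
by default the knee of the IE decay curve, where noise is gone but
structure has not yet eroded. The filtered slice yields an 11-feature
descriptor — mean, SD, histogram entropy (bits), skewness, kurtosis,
GLCM energy, contrast, inverse difference moment, directional moment,
correlation, and a log-scale coarseness — which feeds a soft-margin
RBF-kernel SVM. Localization thresholds the filtered slice (Otsu inside
the eroded head region, floored at median + 2.5·1.4826·MAD), opens and
closes with a disk, and keeps the largest connected component. The
methods vignette (`vignettes/tumor-detection-pipeline.Rmd`) derives and
motivates every choice.

## Worked example

```r
library(tumorscan)

# a seeded 128x128 phantom slice with a known tumor disk
ph  <- generate_phantom(phantom_spec(seed = 1, noise_sigma = 0.03))
enh <- contrast_stretch(ph$image)
den <- anisotropic_filter(enh, diffusion_params())
den
#> <diffusion_result> 128x128 image, 6 iteration(s), final IE 0.0179 (tol 0.02)

res <- localize_tumor(den$image, ph$image)
res
#> <tumor_result> area 534 px, centroid (47.9, 80.3), bbox rows 35..60 cols 68..93, threshold 0.641
dice(res$mask, ph$mask)
#> [1] 0.911315

round(feature_vector(den$image), 4)
#>        mean          sd     entropy    skewness    kurtosis      energy
#>      0.2807      0.2357      1.6130      0.1334      1.7510      0.3543
#>    contrast         idm          dm correlation  coarseness
#>      0.2021      0.9633      0.0944      0.9670   -243.8330
```

The diffusion stopped after 6 sweeps at the IE knee; the recovered
tumor mask overlaps the ground-truth disk with Dice 0.91 and its
centroid (47.9, 80.3) sits within a pixel of the seeded center; the
feature vector is what the classifier consumes (coarseness is reported
on the log2 scale — see `?coarseness`).

For a full experiment, `run_pipeline()` takes a config list or YAML
file, runs enhance → denoise → features → train/evaluate (plus
per-image denoising quality and tumor localization on phantoms), and
returns a JSON-serializable report with the confusion matrix, accuracy
and all resolved parameters. A command-line front end with
per-stage subcommands (`enhance`, `denoise`, `features`, `segment`,
`quality`, `phantom`, `train`, `evaluate`, `run`) is installed at
`inst/cli/tumorscan`.

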