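# kfls

Automated two-stage segmentation of 2D grayscale images corrupted by
**intensity inhomogeneity** — the smooth multiplicative shading ("bias
field") that makes tissue intensity ranges overlap in MRI, CT and X-ray
images and defeats plain thresholding or clustering. The package is aimed
at image-analysis practitioners who need a fully automatic, reproducible
segmentation of a single region of interest together with an estimate of
the bias field.

## Method

The observed image is modelled as

    I(x) = b(x) · J(x) + n(x)

with `J` piecewise constant (region constants `c1`, `c2`), `b` a smooth
multiplicative bias, and `n` additive zero-mean Gaussian noise. The
pipeline has two stages:

1. **Gaussian kernel-based fuzzy c-means (GKFCM).** Pixel intensities are
   clustered by minimizing
   `J_m = 2 Σ_i Σ_k u_ik^m [1 − K(x_k, v_i)]` with the GRBF kernel
   `K(x, v) = exp(−(x − v)²/σ²)` and the automatic width
   `σ² = (max x − min x)² / n`. Defuzzification (max membership) yields a
   crisp region-of-interest mask `A_k`, from which the initial level set
   `φ0 = −c0·A_k + (1 − A_k)·c0` (`c0 = 4`) and the controlling parameters
   are derived automatically: `τ = area(φ0)/length(φ0)`, time step
   `μ = 0.2/τ` (so `μ·τ = 0.2 < 0.25`, the stability bound), length weight
   `λ = 1/τ`, data weight `ν = 1`.
2. **Level-set evolution with bias-field estimation.** The contour (zero
   set of `φ`, ROI = `{φ < 0}`) evolves under
   `φ_t = ν δ_ε(φ)(e1 − e2) + λ δ_ε(φ) κ + μ_R (∇²φ − κ)`,
   where the data forces `e_i = I²·1_K − 2 c_i I (b∗K_σ) + c_i² (b²∗K_σ)`
   come from a kernel-localized fitting energy whose minimization
   alternately updates the two region constants `c1`, `c2` and the bias
   field `b`. The result is the final mask, the estimated bias field, and
   the bias-corrected image `I/b`.

A synthetic phantom generator realizes the image model with known ground
truth, so the whole pipeline is verifiable without external data; `dice()`
and `bias_recovery_score()` quantify mask overlap and shading recovery.
The methods vignette (`vignettes/kernel-fuzzy-level-set.Rmd`) documents
the model, parameter conventions and numerical choices in detail.

## Worked example

```r
library(kfls)

ph  <- make_phantom(seed = 1)   # 128x128 disk phantom, intensities 0.35/0.65,
                                # 40% linear-ramp bias, noise sd 0.02
seg <- segment(ph$image, reference = phantom_mask(ph))
seg
#> kfls segmentation of 128 x 128 image
#>   gkfcm: c = 2, centroids 0.2888/0.5424, roi cluster 2
#>   params: tau = 27.98, mu = 0.007148, lambda = 0.03574, nu = 1 (mu*tau = 0.2)
#>   evolution: 140 iterations, 4628 mask pixels
#>   Dice vs reference: 1.0000 (initial GKFCM mask: 0.7006)

bias_recovery_score(seg$result$b, ph$bias)
#> [1] 0.9883
```

Reading the output: the clustering alone mislabels the brightly shaded
background (Dice 0.70 — under a 40% ramp the two regions' intensity
histograms overlap, so no intensity rule can separate them), the derived
time step satisfies the stability rule exactly (`mu*tau = 0.2`), and the
bias-aware evolution recovers the true disk (Dice 1.00) along with the
shading field (correlation 0.99 with the true ramp). `segment()` also
accepts PNG/TIFF paths, a YAML config, and an `outdir` to write the mask,
bias field, corrected image and a JSON run report.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/kfls.R", package = "kfls"))')" \
    segment --input img.png --reference truth.png --outdir out/
# subcommands: segment, phantom, evaluate; exit codes: 0 ok, 2 config, 3 degenerate input
```

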