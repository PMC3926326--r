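---
title: "Kernel fuzzy c-means initialized level-set segmentation with bias-field estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel fuzzy c-means initialized level-set segmentation with bias-field estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfls)
```

## The problem

Region-based segmentation of medical images (MRI, CT, X-ray) assumes that a
tissue class has a roughly constant intensity. Real scanners violate this:
a smooth multiplicative shading — the *bias field* or *intensity
inhomogeneity* — makes the histogram ranges of distinct tissues overlap, so
no single intensity threshold, and no pure intensity clustering, can
separate them. `kfls` implements a two-stage pipeline for this situation:

1. **Coarse stage.** A Gaussian kernel-based fuzzy c-means (GKFCM)
   clustering of the pixel intensities, with the kernel width estimated
   automatically from the data, gives an approximate contour of the region
   of interest (ROI) and — through the contour's geometry — the controlling
   parameters of the second stage.
2. **Fine stage.** A level-set evolution driven by a localized region
   energy that *jointly* estimates the segmentation and the bias field, so
   the contour can cross intensity ranges that the clustering cannot.

The observed image is modelled as

$$I(x) = b(x)\,J(x) + n(x),$$

where $J$ is the true piecewise-constant image (tissue constants $c_1,
c_2$), $b$ is the smooth multiplicative bias, and $n$ is additive zero-mean
Gaussian noise. The synthetic generator `make_phantom()` realizes exactly
this model with known ground truth, which is how the package verifies
itself end to end.

## Stage one: GKFCM

Fuzzy c-means assigns each pixel $x_k$ a membership $u_{ik} \in [0,1]$ in
each cluster $i$ (columns summing to 1) and minimizes, in the kernelized
form,

$$J_m(U, V) = 2 \sum_{i=1}^{c} \sum_{k=1}^{n} u_{ik}^m\,[1 - K(x_k, v_i)],
\qquad K(x, v) = \exp(-\|x - v\|^2 / \sigma^2),$$

with fuzzifier $m = 2$. The kernel width is estimated from the data as
$\sigma^2 = (\max_k x_k - \min_k x_k)^2 / n$, so the user supplies nothing
beyond the cluster count. Alternating the closed-form membership update
with the fixed-point centroid update (a kernel-weighted mean, one sweep per
cycle) monotonically decreases $J_m$; for the Gaussian kernel the centroid
sweep is a mean-shift/EM-type step, which guarantees descent. Convergence
is declared on the centroids (default tolerance `1e-5` on the maximum
centroid change, at most 100 cycles), since the memberships are a
deterministic function of the centroids. Centroids are initialized at
evenly spaced quantiles of the intensity distribution, making the fit fully
deterministic; the `seed` argument only governs the rare reseeding of a
centroid whose weight mass collapses.

### Numerical behavior of the automatic kernel width

Because $\sigma^2$ shrinks like $1/n$, on a whole image the kernel is
extremely sharp (about $3\times10^{-5}$ squared intensity units on a
$128 \times 128$ frame). Consequences:

- For a pixel more than a few kernel widths from *every* centroid,
  $1 - K$ rounds to exactly 1 in double precision and the stored
  memberships saturate at $1/c$ per cluster. This is a representation
  limit, not a modelling choice.
- The max-membership rule still has a well-defined answer, because
  memberships are strictly monotone in the distance to the centroid.
  `defuzzify()` on a fitted partition therefore evaluates the argmax in
  exact arithmetic (equivalently: nearest centroid), rather than comparing
  the saturated stored values. On a bare membership matrix, `defuzzify()`
  is a plain per-column argmax with ties broken toward the lowest class
  index.
- $1 - K$ is clipped below at $10^{-12}$ before the $-1/(m-1)$ power, so a
  pixel coinciding exactly with a centroid receives (essentially) full
  membership there, split equally if several centroids coincide.

## The bridge: initialization and automatic parameters

Defuzzification gives a crisp labeling; the ROI class is chosen as the
brightest centroid by default (`select_roi_cluster()`, overridable to an
explicit index). With $A_k$ the binary ROI mask, the initial level set is
the binary step

$$\phi_0 = -c_0 A_k + (1 - A_k)\,c_0, \qquad c_0 = 4,$$

negative inside the ROI. From $\phi_0$ the evolution parameters are derived
automatically via the area-to-length ratio

$$\tau = \frac{\mathrm{area}(\phi_0)}{\mathrm{length}(\phi_0)}, \qquad
\mu = \frac{0.2}{\tau}, \quad \lambda = \frac{1}{\tau}, \quad \nu = 1,$$

where the area is the crisp pixel count on the ROI side and the length is
the smoothed Dirac integral $\sum_x \delta_\epsilon(\phi_0)$ over the grid
($\epsilon = 1$). $\mu$ is the time step; the construction gives
$\mu\tau = 0.2$, strictly below the $0.25$ stability bound, for every
input. Two conventions deserve a note:

- The area integral is taken over the ROI ($\phi_0 < 0$), consistent with
  reading $\tau$ as the ROI's area-to-length ratio. (Taking it over
  $\{\phi_0 \ge 0\}$ instead would only rescale $\tau$; the stability
  product $\mu\tau$ is unaffected either way.)
- With a binary-step $\phi_0$ the Dirac term is constant on each side, so
  the "length" is dominated by the off-contour plateau; this is the price
  of the step initialization, and it is harmless because only the ratio's
  order of magnitude matters for the time step.

## Stage two: level-set evolution with bias-field estimation

The ROI is $\{\phi < 0\}$ with smooth indicator $M_1 = 1 - H_\epsilon(\phi)$,
the exterior $M_2 = H_\epsilon(\phi)$, using the arctangent Heaviside
$H_\epsilon(\phi) = \tfrac12[1 + \tfrac{2}{\pi}\arctan(\phi/\epsilon)]$ and
its derivative $\delta_\epsilon$. Each iteration performs four updates, in
this order (each is the variational minimizer — or a one-step surrogate —
of the localized energy given the others):

1. **Region constants.**
   $c_i = \sum_x (b * K_\sigma)(x) I(x) M_i(x) \big/ \sum_x (b^2 * K_\sigma)(x) M_i(x)$.
   These are the two tissue constants of the image model; all spatial
   variation is carried by $b$.
2. **Bias field.**
   $b = K_\sigma * \big(I\,(c_1 M_1 + c_2 M_2)\big) \big/ K_\sigma * \big(c_1^2 M_1 + c_2^2 M_2\big)$,
   clipped to $[10^{-3}, 10^{3}]$ so the bias-corrected image $I/b$ stays
   defined.
3. **Data forces.**
   $e_i(x) = I^2 1_K - 2 c_i I (b * K_\sigma) + c_i^2 (b^2 * K_\sigma)$,
   the kernel-weighted residual $\sum_y K_\sigma(y-x)[I(x) - b(y) c_i]^2$.
4. **Level-set step.**
   $\phi \leftarrow \phi + \mu\,[\nu s^2 \delta_\epsilon(\phi)(e_1 - e_2)
   + \lambda \delta_\epsilon(\phi)\,\kappa + \mu_R(\nabla^2\phi - \kappa)]$,
   with curvature $\kappa = \mathrm{div}(\nabla\phi/|\nabla\phi|)$ and
   $s$ the intensity scale (below). Where $e_1 < e_2$ the pixel fits the
   ROI model better and $\phi$ decreases there.

Evolution stops when the zero-level mask changes by less than `stop_tol`
(default $10^{-4}$ of all pixels) for 10 consecutive iterations, or after
`max_iter` (default 500) steps.

### Design choices that were genuinely open

**Region constants are scalars, not fields.** A localized model could also
let $c_1, c_2$ vary per pixel (the local-binary-fitting family). We
prototyped both: with per-pixel means, a large misclassified region
inherited from the coarse stage becomes self-consistent — its local "ROI
mean" is simply its own intensity — and the contour stalls. With two global
constants the misfit is visible to the force at any distance, and the
kernel-smoothed bias field alone carries the spatial adaptation. The
two-constants form is also what the image model states. This choice is
what lets the fine stage correct the coarse stage.

**The bias smoothing scale `sigma_K` tracks the image size.** The only
thing separating "bias" from "signal" in a multiplicative model is
smoothness. If $K_\sigma$ is a few pixels wide, $b$ can absorb
segmentation errors and even noise (on phantoms, a 3 px kernel reproduces
the true shading with correlation under 0.5 even from a perfect contour),
and the decomposition is unidentifiable. A shading field varies at the
scale of the field of view, so the default is
$\sigma_K = \max(3, \min(\text{rows}, \text{cols})/6)$ — about 21 px on a
$128\times128$ image — overridable via `evolve.sigma_K`. The kernel is
truncated at radius $\lceil 4\sigma_K \rceil$ and renormalized.

**Intensity scale of the force balance.** The data forces have units of
intensity$^2$ while the length and regularization terms are geometric. The
automatic rules $\nu = 1$, $\lambda = 1/\tau$ were calibrated for images on
their native 8-bit range; this package normalizes images to $[0,1]$, which
would shrink the data force by $255^2$ relative to that balance and leave
the contour effectively frozen within any practical iteration budget. The
data term is therefore evaluated on the 8-bit scale through the factor
$s^2$ (`intensity_scale = 255`, configurable), which restores the intended
dimensionless balance while keeping $\nu = 1$.

**Distance regularization.** The single-well potential
$p(s) = (s-1)^2/2$ yields the $(\nabla^2\phi - \kappa)$ regularization that
keeps $\phi$ near a signed distance function without reinitialization. Its
weight $\mu_R = 1$ is kept separate from the time step: the derived $\mu$
plays only the time-step role, and the stability product $\mu\tau = 0.2$
refers to it.

**Zero padding for all $K_\sigma$ convolutions.** With domain-restricted
sums, $e_i$ is exactly $\sum_{y\in\Omega} K(y-x)[I(x) - b(y)c_i]^2 \ge 0$
and $1_K \le 1$ with equality in the interior. Replicate padding would
instead mix extrapolated border values into the residuals and can make the
$e_i$ expression negative near corners. Ratio quantities ($c_i$, $b$) are
self-normalizing, so the padding choice does not bias them.

**Other numerical conventions.** Central differences for $\nabla\phi$ and
$\kappa$, 5-point Laplacian, $|\nabla\phi|$ guarded by $10^{-10}$,
homogeneous Neumann boundary for $\phi$, denominators guarded by
$10^{-10}$, $b$ initialized to 1, $\epsilon = 1$ for $H$ and $\delta$.

## The phantom generator

`make_phantom()` draws the study conditions used throughout the tests: a
$128\times128$ two-region image (disk, square, two-blob or ring geometry)
with region constants $0.35/0.65$, a mean-one bias field (`linear_ramp`
with fractional modulation $\beta = 0.4$ by default; also `gaussian_blob`
and `polynomial`), and i.i.d. Gaussian noise of sd $0.02$ — a regime in
which the two regions' intensity histograms overlap, i.e. exactly where
intensity clustering must degrade and the bias-aware stage must not. The
bias amplitude is parameterized as fractional modulation about mean 1
because the model only resolves $b \cdot J$ up to a scale. All randomness
is seeded and the caller's RNG state is preserved.

What the phantom does *not* emulate: anatomical texture, partial-volume
boundaries, spatially correlated or Rician noise, and multi-class anatomy.
Passing the phantom suite therefore demonstrates correctness of the
mechanics (model recovery under multiplicative shading and additive
Gaussian noise), not clinical-grade accuracy on real scans.

## Evaluation

`dice()` computes $2|A\cap B|/(|A|+|B|)$ (two empty masks score 1 by
convention) and `bias_recovery_score()` the Pearson correlation of
mean-normalized bias fields, the natural scale-free comparison under the
model's $b$-vs-$c$ scale ambiguity.

## Problem sizes used by the test suite

The bundled tests run entirely on generated data: the recovery checks use
ten $128\times128$ phantoms segmented end to end (about 10 s each), the
long-run stability check uses twenty $32\times32$ phantoms for 1000
iterations, and the brute-force oracle comparisons use $16\times16$ inputs
where the double-sum oracles are exact but cheap. These sizes were chosen
so that the whole suite documents the method's behavior in minutes while
still exercising every code path at realistic aspect ratios.

## Known limitations

- Two-phase segmentation only (one ROI class against background); no
  multiphase level sets, no 3D volumes, no narrow-band acceleration.
- The coarse stage uses intensity only (no spatial regularization), so its
  initial mask can be badly wrong under strong bias — by design, the fine
  stage is what corrects it, but a pathological initialization (empty or
  full ROI) aborts the pipeline with a degenerate-input error.
- The automatic $\sigma^2$ rule makes the kernel sharpness grow with image
  size; for very large images the coarse stage approaches a nearest-
  centroid quantizer.
- Bias fields rougher than the $\sigma_K$ smoothing scale cannot be
  recovered and will instead distort the contour.

## A worked example

```{r example}
ph <- make_phantom(seed = 1)          # 128x128 disk, 40% ramp, noise 0.02
seg <- segment(ph$image, reference = phantom_mask(ph))
seg
bias_recovery_score(seg$result$b, ph$bias)
```

The report shows the derived parameters (with $\mu\tau = 0.2$), the
iteration count at stabilization, and the Dice of the final mask against
the ground truth next to the Dice of the clustering-only mask — the gap
between the two is the contribution of the bias-aware evolution.
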