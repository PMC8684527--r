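---
title: "Multifocus image fusion with sharpening preprocessing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifocus image fusion with sharpening preprocessing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalfuse)
```

## The problem

A camera with a finite depth of field cannot hold an entire scene in focus:
two photographs of the same scene taken with different focus settings each
contain a sharp region and a defocus-blurred region. Multifocus image fusion
combines two such registered source images into a single all-in-focus image.
`focalfuse` implements a complete pipeline for this task: an optional
sharpening preprocessing step applied to both sources, four fusion back-ends,
an eight-metric full-reference quality suite, and a seeded synthetic
generator that provides ground truth for end-to-end evaluation.

All images are plain numeric matrices (grayscale) or `M x N x 3` arrays
(RGB), floating point on the `[0, 255]` scale, indexed `(row, col)` with row
1 at the top. RGB images are processed per channel throughout — sharpening,
fusion, and the per-band metric terms — which is the conservative choice when
no color transform is mandated.

## Sharpening preprocessors

Three sharpeners are available through `sharpen_config()`:

* **Laplacian** (`laplacian`): the discrete second-derivative response
  `L = k ⊗ I` with the 3x3 stencil `k` (four-neighbor, center -4, or
  eight-neighbor, center -8), and output `clip(I - gain * L)`. The
  subtraction adds edge contrast because the stencils have negative centers.
* **Unsharp masking** (`unsharp`): `clip(I + gain * (I - G_sigma ⊗ I))`,
  where `G_sigma` is a separable Gaussian truncated at 4 standard deviations
  and renormalized. `gain` is the positive scaling factor controlling the
  contrast boost; the image size is unchanged.
* **Hybrid Laplacian + DFT** (`lf_dft`): the cross-domain sharpener. The
  image is transformed with the unnormalized 2-D DFT (negative exponent;
  `F(0,0)` is the sum of all pixels), multiplied by the frequency response of
  the Laplacian stencil (the convolution-theorem equivalent of spatial
  filtering), optionally re-weighted by a radial emphasis window, inverse
  transformed (with `1/(MN)` normalization), and subtracted:
  `clip(I - gain * Re(IDFT(W * H_lap * DFT(I))))`.

The hybrid formulation combines the second-derivative edge localization of
the Laplacian with explicit access to the frequency axis. Taken literally —
transform the Laplacian-filtered image and transform back — it reduces to the
plain Laplacian, so the design question is what the frequency-domain step
should add. This package realizes it as the emphasis window
`W(u, v) = r(u, v) / r_max`, the centered radial frequency distance
normalized so DC has weight 0 and the Nyquist corner weight 1. It suppresses
the correction at low frequencies (where defocus blur lives and sharpening
mostly amplifies shading) and preserves it at high frequencies (edges and
texture). With `emphasis = FALSE` the hybrid path is mathematically identical
to the spatial Laplacian under circular boundary extension — this identity is
tested to 1e-6 over 100 seeded images and is the oracle that pins the
frequency-domain implementation to the spatial one. Note that because
`W <= 1`, emphasis can only redistribute, never increase, the correction
energy: a pure Nyquist checkerboard is left unchanged and low-frequency
patterns are strictly attenuated.

Defaults (`gain = 1`, `sigma = 1`, four-neighbor stencil, reflect boundary
for the spatial sharpeners, emphasis on for `lf_dft`) are package choices:
sensible middle-of-the-road values for 8-bit photographs; no authoritative
values exist for these parameters. `gain` trades sharpness against overshoot
(values above ~2 visibly halo on hard edges); `sigma` sets the spatial scale
of detail that unsharp masking amplifies.

## Wavelet transforms and fusion rules

The transform back-ends decompose each source into an approximation and
per-level {horizontal, vertical, diagonal} detail subbands:

* **DWT**: the decimated transform; level-`l` subbands have extent
  `ceiling(M / 2^l)`. Fast and orthogonal, but not shift-invariant — a
  one-pixel translation of the inputs changes the fused output, which the
  test suite demonstrates on a step-edge scene.
* **SWT**: the undecimated ("à trous") transform, which upsamples the filters
  instead of downsampling the data; every subband keeps the full image
  extent and the transform commutes exactly with circular shifts.

Both use orthonormal Daubechies filters (`db1`/haar, `db2`, `db4`) and
periodic (circular) signal extension, implemented in the package. Under
periodization the orthonormal filter bank is an exact orthonormal basis of
the finite grid, so perfect reconstruction holds to floating-point precision
(tested at 1e-8, measured near 1e-10); the same property makes SWT
shift-equivariance exactly testable. Odd DWT extents are handled by
duplicating the last sample per level; SWT inputs are symmetrically padded to
a multiple of `2^levels` and cropped after reconstruction. The SWT inverse
exploits the quadrature-mirror identity `|H(w)|^2 + |G(w)|^2 = 2`, which
makes the circular synthesis (conjugate transfer functions, divided by 2 per
dimension) exact at every frequency; both analysis and synthesis are
evaluated via the FFT.

Coefficient fusion (`fuse_coefficients()`) combines the two pyramids
elementwise: approximation by the **mean**, details by **maximum-absolute
selection** (ties broken toward the first source). This is the standard rule
pair for multifocus fusion — the in-focus source carries the larger detail
magnitudes, so max-abs selection transplants sharp structure while the mean
stabilizes the low-frequency content; both rules are configurable
(`approx_rule`, `detail_rule`). Defaults `wavelet = "db2"`, `levels = 2` are
package choices: a short filter with exact reconstruction, and a depth
typical for the 512-pixel-class images this pipeline targets.

The spatial-domain baselines are the pixelwise `fuse_average()` (robust,
low-contrast) and `fuse_minimum()` (retains dark detail, biased downward).

## Quality metrics

`evaluate_all()` scores a fused image `If` against a true all-in-focus
reference `Iz` (plus the two sources for MAE):

| metric | formula | better |
|---|---|---|
| RMSE | `sqrt(mean((Iz - If)^2))` | lower |
| PFE | `(||Iz-If||/||Iz|| + ||Iz-If||/||If||) * 100` | lower |
| MAE | `mean(|Ia - If|) + mean(|Ib - If|)` | lower |
| entropy | `-sum p_k log2 p_k` over 256 grey bins | higher |
| SNR | `10 log10(sum Iz^2 / sum (Iz-If)^2)` | higher |
| PSNR | `10 log10(255^2 / MSE)` | higher |
| CC | `2 sum(Iz*If) / (sum Iz^2 + sum If^2)` | near 1 |
| ERGAS | `100 (dh/dl) sqrt(mean_i(RMSE_i^2 / mean_i^2))` | lower |

Several formulas deviate from common practice and both variants are
implemented, with the variant recorded in the report:

* **PSNR** defaults to the conventional `10 log10((G-1)^2 / MSE)` form —
  the only form consistent with the 26–44 dB range that fused 8-bit images
  actually produce; the literal `20 log10(G^2 / MSE)` form is available as
  `variant = "printed"`.
* **PFE** defaults to the two-term form above; the conventional single-term
  `||Iz-If||/||Iz|| * 100` sits behind `variant = "conventional"`. The two
  coincide at 0 on equality and differ by roughly a factor 2 otherwise.
* **MAE** is the two-term sum of deviations from *both* sources (so it is 0
  only when the fused image equals both), with a single-reference variant.
* **CC** is an energy-normalized similarity, not Pearson correlation: it
  equals `2a/(1+a^2)` for `If = a * Iz`, a closed form the tests check.
* **entropy** uses log base 2 (bits), so its ceiling is 8 for 8-bit images.
* **ERGAS** uses resolution ratio `dh/dl = 1`, appropriate when both inputs
  share one resolution.

Metrics needing a true image take it explicitly; real multifocus pairs have
no all-in-focus reference, which is why quantitative evaluation here runs on
synthetic scenes.

## The synthetic generator

`make_fixture()` builds a scene with known ground truth: a deterministic
textured image (background gradient, random rectangles, ellipses and oriented
sinusoidal gratings — at least one grating per quadrant so both halves carry
high-frequency content — plus Gaussian texture noise with sd 2.5), a focus
mask, and the two sources

```
B = gaussian_blur(gt, blur_sigma)
source_a = mask * gt + (1 - mask) * B
source_b = (1 - mask) * gt + mask * B
```

so `source_a + source_b = gt + B` exactly, an algebraic identity the tests
verify. Defocus is modeled as fixed-sigma Gaussian blur blended by the mask —
the standard simulation for multifocus benchmarks — not a physical thin-lens
point-spread function; depth-dependent blur, misregistration, sensor noise
and demosaicing artifacts of real camera pairs are *not* emulated, so passing
tests certify the pipeline's mathematics, not field performance on arbitrary
photographs. Presets: `gray512` (512 x 512 grayscale), `rgb520`
(520 x 520 RGB) — the two frame classes this kind of benchmark uses — and
`tiny64` for fast unit tests. Defaults `blur_sigma = 3` px (clearly visible
defocus at this scale) and a hard half-field mask (`transition_width = 0`)
are package choices; every operation is a pure function of
`(preset, seed, parameters)` and leaves the caller's RNG state untouched.

## Numerical choices and degenerate inputs

* Saving quantizes with round-half-to-even and clips to `[0, 255]`;
  `load(save(x))` equals `clip(round(x))` bitwise.
* `max_abs` coefficient ties go to the first source, making fusion of
  identical pyramids exactly idempotent.
* SNR/PSNR report `Inf` when the images are equal; PFE, CC and ERGAS refuse
  all-zero (or zero-mean, for ERGAS) references rather than returning
  arbitrary numbers.
* The DFT path is exact circular convolution, so the hybrid sharpener's
  oracle equivalence uses `boundary = "circular"`; the spatial default is
  `reflect`, which avoids wrap-around halos on photographs.
* Constant images are fixed points of every sharpener (blur of a constant is
  itself; the Laplacian of a constant is 0).

## Scale of the shipped experiments

The test suite and the acceptance script run the full 10-combination grid
(average, minimum, DWT, SWT, and DWT/SWT preceded by each of the three
sharpeners, scored by all eight metrics) on one `gray512` scene — about
four seconds of compute — and exercise the transform oracles on 8 x 8
(brute-force double sums) to 64 x 64 (perfect-reconstruction and
shift-equivariance properties) images; these sizes make every property
checkable to tight tolerances while keeping a full run near ten seconds.

## Known limitations

* Sharpening before fusion *reduces* fidelity to an unsharpened ground truth
  by construction (the sharpened sources are no longer samples of it), so on
  synthetic scenes the plain SWT rows win RMSE-family metrics while sharpened
  rows win only when judged against sharpened references or by no-reference
  criteria such as entropy. The package reports the metrics; it does not
  adjudicate this.
* Two sources only; block-based focus-measure fusion, guided-filter
  post-processing and >2-image stacks are out of scope.
* Sources must be registered; no alignment is attempted.
* Supported wavelets are db1/db2/db4; the transform code is written for
  orthonormal filters and would need extension for biorthogonal pairs.
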