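# focalfuse

Multifocus image fusion for R: combine two registered photographs of one
scene, each with a different region in focus, into a single all-in-focus
image — with optional sharpening preprocessing, wavelet-domain coefficient
fusion, and a full-reference quality suite.

## What it does

A finite depth of field leaves part of every photograph defocus-blurred.
Given two registered sources `Ia`, `Ib` with complementary focus, `focalfuse`
provides:

* **Sharpening preprocessors** applied to both sources before fusion:
  Laplacian filtering (`clip(I − gain · k ⊗ I)` with a 3×3 second-derivative
  stencil `k`), unsharp masking (`clip(I + gain · (I − G_σ ⊗ I))`), and a
  hybrid Laplacian + DFT sharpener that applies the Laplacian transfer
  function in the Fourier domain with a radial high-frequency emphasis window
  `W(u,v) = r(u,v)/r_max`.
* **Fusion back-ends**: pixelwise average and minimum, and wavelet-domain
  fusion with the decimated DWT or the shift-invariant stationary wavelet
  transform (SWT), using orthonormal Daubechies filters (db1/db2/db4) with
  exact perfect reconstruction. Approximation coefficients are fused by the
  mean, detail coefficients by maximum-absolute selection.
* **Eight quality metrics** against a true all-in-focus reference: RMSE, PFE,
  MAE, entropy, SNR, PSNR, CC (energy-normalized correlation) and ERGAS,
  including documented formula variants.
* **A seeded synthetic generator**: a textured ground-truth scene and two
  sources produced by complementary region-wise Gaussian defocus
  (`source_a = mask·gt + (1−mask)·blur(gt)`, source B the complement), so the
  whole pipeline is quantitatively testable without any external dataset.
* **A CLI** (`inst/cli/focalfuse`) with `sharpen`, `fuse`, `evaluate` and
  `demo` subcommands.

## Worked example

```r
library(focalfuse)

# synthetic 512 x 512 scene: left half of source A in focus, sigma-3 defocus
scene <- make_fixture("gray512", seed = 42L, blur_sigma = 3)

fused <- fuse(scene$pair, fuse_config("swt"), sharpen_config("none"))
evaluate_all(scene$pair$source_a, scene$pair$source_b, fused,
             scene$ground_truth)
#> <quality_report>
#>   rmse     5.65524
#>   pfe      8.24359
#>   mae      9.29552
#>   entropy  7.05296
#>   snr      27.7218
#>   psnr     33.0818
#>   cc       0.999151
#>   ergas    4.30807

rmse(scene$ground_truth, scene$pair$source_a)  # 13.15748
rmse(scene$ground_truth, scene$pair$source_b)  #  9.072661
```

The fused RMSE (5.66 grey levels) is well below either blurred source (13.16
and 9.07): max-abs detail selection in the SWT domain transplants the sharp
structure of each source into one image. PSNR of 33.1 dB and CC of 0.9992
say the fused image is close to the true scene; entropy of 7.05 bits reflects
its texture content.

The same grid the CLI demo produces — all ten (fusion method, sharpener)
combinations by all eight metrics — comes from:

```r
demo_grid(scene)            # 10 x 10 data frame
```

or from the shell:

```sh
Rscript inst/cli/focalfuse demo --preset gray512 --seed 42 \
    --out grid.csv --markdown grid.md
Rscript inst/cli/focalfuse fuse --input-a a.png --input-b b.png \
    --method swt --sharpen lf_dft --out fused.png
```

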