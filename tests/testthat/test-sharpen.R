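test_that("Laplacian response vanishes on constants and linear ramps", {
  cfg <- sharpen_config("laplacian")
  expect_equal(laplacian_response(const_img(100), cfg),
               const_img(0), tolerance = 1e-12)
  # horizontal linear ramp: interior second derivative is zero
  ramp <- matrix(rep(seq(0, 150, length.out = 16), each = 16), 16, 16)
  resp <- laplacian_response(ramp, sharpen_config("laplacian",
                                                  boundary = "circular"))
  expect_equal(max(abs(resp[, 2:15])), 0, tolerance = 1e-10)
})

test_that("unit impulse reproduces the Laplacian stencil", {
  for (variant in c("four_neighbor", "eight_neighbor")) {
    img <- matrix(0, 9, 9)
    img[5, 5] <- 1
    cfg <- sharpen_config("laplacian", kernel_variant = variant)
    resp <- laplacian_response(img, cfg)
    expect_equal(resp[4:6, 4:6], laplacian_kernel(variant), tolerance = 1e-12)
    expect_equal(sum(abs(resp)), sum(abs(laplacian_kernel(variant))),
                 tolerance = 1e-12)
  }
})

test_that("all three sharpeners are the identity on constant images", {
  img <- const_img(100)
  for (m in c("laplacian", "unsharp", "lf_dft")) {
    for (emph in c(TRUE, FALSE)) {
      cfg <- sharpen_config(m, emphasis = emph)
      expect_equal(sharpen_image(img, cfg), img, tolerance = 1e-9,
                   label = paste(m, emph))
    }
  }
})

test_that("Laplacian sharpening overshoots across a hard step edge", {
  img <- step_img(16, 16, 0, 255)
  cfg <- sharpen_config("laplacian", gain = 1)
  pre <- img - cfg$gain * laplacian_response(img, cfg)
  expect_lt(min(pre), 0)     # undershoot on the dark side
  expect_gt(max(pre), 255)   # overshoot on the bright side
  out <- sharpen_laplacian(img, cfg)
  expect_true(all(out >= 0 & out <= 255))
})

test_that("edge contrast is nondecreasing in gain for every sharpener", {
  img <- step_img(16, 16, 110, 140)  # modest step: no clipping at these gains
  gains <- c(0.25, 0.5, 1, 2)
  for (m in c("laplacian", "unsharp", "lf_dft")) {
    contrast <- vapply(gains, function(g) {
      out <- sharpen_image(img, sharpen_config(m, gain = g))
      max(out) - min(out)
    }, numeric(1))
    expect_true(all(diff(contrast) >= -1e-9), label = m)
    expect_gt(contrast[length(gains)], contrast[1])
  }
})

test_that("unsharp masking approaches the identity as gain vanishes", {
  img <- rand_img(16, seed = 7)
  out <- sharpen_unsharp(img, sharpen_config("unsharp", gain = 1e-9))
  expect_equal(out, clip_to_range(img), tolerance = 1e-6)
})

test_that("unsharp masking preserves column-only structure (separability)", {
  img <- matrix(rep(rand_img(1, 24, seed = 5), each = 24), 24, 24)
  out <- sharpen_unsharp(img, sharpen_config("unsharp", sigma = 1.5))
  # every row should be identical since filtering is separable
  expect_equal(max(apply(out, 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-10)
  expect_identical(dim(out), dim(img))
})

test_that("gaussian_blur preserves constants and the global mean (circular)", {
  expect_equal(gaussian_blur(const_img(42), 2), const_img(42),
               tolerance = 1e-12)
  img <- rand_img(32, seed = 9)
  expect_equal(mean(gaussian_blur(img, 3, "circular")), mean(img),
               tolerance = 1e-10)
})

test_that("dft2 has the correct DC, symmetry and Nyquist structure", {
  co <- dft2(const_img(7, 6, 4))$coefficients
  expect_equal(co[1, 1], 7 * 24 + 0i, tolerance = 1e-10)
  expect_lt(max(Mod(co[-1])), 1e-9)

  x <- rand_img(8, seed = 11)
  S <- dft2(x)$coefficients
  # Hermitian symmetry of the spectrum of a real image
  for (u in 0:7) {
    for (v in 0:7) {
      expect_equal(S[u + 1, v + 1],
                   Conj(S[((8 - u) %% 8) + 1, ((8 - v) %% 8) + 1]),
                   tolerance = 1e-8)
    }
  }

  # 4x4 checkerboard: all AC energy sits at the Nyquist bin (M/2, N/2); the
  # 0/255 pattern also carries its mean at DC, verified by the brute-force sum
  cb <- 255 * outer(0:3, 0:3, function(i, j) (i + j) %% 2)
  Scb <- dft2(cb)$coefficients
  expect_lt(max(Mod(Scb - brute_dft2(cb))), 1e-9)
  expect_equal(Mod(Scb[3, 3]), 16 * 127.5, tolerance = 1e-9)
  expect_equal(Scb[1, 1], sum(cb) + 0i, tolerance = 1e-9)
  Scb[3, 3] <- 0
  Scb[1, 1] <- 0
  expect_lt(max(Mod(Scb)), 1e-9)
  # the zero-mean checkerboard is exactly the sole-Nyquist-bin case
  Szm <- dft2(cb - 127.5)$coefficients
  expect_equal(Mod(Szm[3, 3]), 16 * 127.5, tolerance = 1e-9)
  Szm[3, 3] <- 0
  expect_lt(max(Mod(Szm)), 1e-9)
})

test_that("dft2/idft2 match the brute-force double sums on random 8x8 images", {
  for (seed in 1:3) {
    x <- rand_img(8, seed = seed)
    S <- dft2(x)$coefficients
    expect_lt(max(Mod(S - brute_dft2(x))), 1e-8)
    expect_lt(max(abs(idft2(dft2(x)) - Re(brute_idft2(S)))), 1e-8)
    expect_equal(idft2(dft2(x)), x, tolerance = 1e-12)
  }
})

test_that("idft2 reconstructs a constant from a DC-only spectrum", {
  S <- matrix(0 + 0i, 8, 8)
  S[1, 1] <- 64 * 3.5
  expect_equal(idft2(structure(list(coefficients = S),
                               class = "spectral_image")),
               const_img(3.5, 8), tolerance = 1e-12)
})

test_that("transforms satisfy Parseval's identity", {
  for (seed in 1:5) {
    x <- rand_img(16, 12, seed = seed)
    S <- dft2(x)$coefficients
    expect_equal(sum(x^2), sum(Mod(S)^2) / length(x),
                 tolerance = 1e-9)
  }
})

test_that("dft2 refuses multi-channel input", {
  expect_error(dft2(array(1, c(8, 8, 3))), "single-channel")
})

test_that("hybrid sharpener equals spatial Laplacian with emphasis off", {
  for (variant in c("four_neighbor", "eight_neighbor")) {
    for (seed in 1:10) {
      img <- rand_img(32, seed = seed)
      cfg <- sharpen_config("lf_dft", gain = 0.7, boundary = "circular",
                            kernel_variant = variant, emphasis = FALSE)
      expect_lt(max(abs(sharpen_lf_dft(img, cfg) -
                          sharpen_laplacian(img, cfg))), 1e-6)
    }
  }
})

test_that("radial emphasis reweights corrections toward high frequencies", {
  M <- 16
  grid <- outer(seq_len(M), seq_len(M), function(i, j) i + j)
  nyq <- 128 + 20 * (-1)^grid                         # checkerboard, Nyquist
  low <- 128 + 20 * sin(2 * pi * seq_len(M) / M) %o% rep(1, M)  # 1st harmonic
  corr_energy <- function(img, emph) {
    cfg <- sharpen_config("lf_dft", gain = 1, emphasis = emph)
    sum((sharpen_lf_dft(img, cfg) - img)^2)
  }
  # emphasis never increases the correction (W <= 1); at the Nyquist corner
  # W = 1 so a pure checkerboard is left unchanged, and a low-frequency
  # pattern is strictly attenuated
  expect_equal(corr_energy(nyq, TRUE), corr_energy(nyq, FALSE),
               tolerance = 1e-9)
  expect_lt(corr_energy(low, TRUE), corr_energy(low, FALSE))
  # with emphasis on, the Nyquist-pattern correction dominates the
  # first-harmonic correction at equal gain
  expect_gt(corr_energy(nyq, TRUE), corr_energy(low, TRUE))
})

test_that("sharpen_config validates its parameters", {
  expect_error(sharpen_config("laplacian", gain = 0), "gain")
  expect_error(sharpen_config("unsharp", sigma = -1), "sigma")
  expect_error(sharpen_config("magic"))
  expect_true(sharpen_config("lf_dft")$emphasis)
  expect_false(sharpen_config("laplacian")$emphasis)
})
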