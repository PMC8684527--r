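# Sharpening preprocessors applied to each source image before fusion:
# Laplacian filtering, unsharp masking, and the hybrid cross-domain sharpener
# that applies the Laplacian transfer function in the Fourier domain with an
# optional radial high-frequency emphasis window.

#' Sharpening configuration
#'
#' @param method one of `"none"`, `"laplacian"`, `"unsharp"`, `"lf_dft"`.
#' @param gain positive scaling factor applied to the correction signal
#'   (the lambda of unsharp masking; also the gain of the Laplacian and
#'   hybrid sharpeners).
#' @param sigma Gaussian radius (pixels) of the unsharp-mask low-pass.
#' @param kernel_variant Laplacian stencil: `"four_neighbor"` (center -4) or
#'   `"eight_neighbor"` (center -8).
#' @param boundary extension used by spatial convolutions: `"reflect"`
#'   (edge-mirrored) or `"circular"` (periodic).
#' @param emphasis logical; apply the radial high-frequency emphasis window in
#'   the hybrid frequency-domain sharpener. Defaults to `TRUE` for
#'   `method = "lf_dft"` and `FALSE` otherwise; only meaningful for that
#'   method.
#' @return an object of class `sharpen_config`.
#' @export
sharpen_config <- function(method = c("none", "laplacian", "unsharp", "lf_dft"),
                           gain = 1.0,
                           sigma = 1.0,
                           kernel_variant = c("four_neighbor", "eight_neighbor"),
                           boundary = c("reflect", "circular"),
                           emphasis = NULL) {
  method <- match.arg(method)
  kernel_variant <- match.arg(kernel_variant)
  boundary <- match.arg(boundary)
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0) {
    stop("gain must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  if (is.null(emphasis)) emphasis <- identical(method, "lf_dft")
  structure(list(method = method, gain = gain, sigma = sigma,
                 kernel_variant = kernel_variant, boundary = boundary,
                 emphasis = isTRUE(emphasis)),
            class = "sharpen_config")
}

#' Discrete Laplacian stencil
#'
#' @param variant `"four_neighbor"` (center -4, N/S/E/W 1) or
#'   `"eight_neighbor"` (center -8, all neighbors 1).
#' @return 3 x 3 numeric matrix.
#' @export
laplacian_kernel <- function(variant = c("four_neighbor", "eight_neighbor")) {
  variant <- match.arg(variant)
  if (variant == "four_neighbor") {
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  } else {
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
  }
}

# index map for boundary extension: positions 1-r .. n+r folded back into 1..n
extend_index <- function(n, r, boundary) {
  i <- seq.int(1 - r, n + r)
  if (boundary == "circular") {
    ((i - 1) %% n) + 1
  } else {
    # half-sample symmetric reflection: ... 2 1 | 1 2 ... n-1 n | n n-1 ...
    period <- 2 * n
    j <- ((i - 1) %% period) + 1
    j[j < 1] <- j[j < 1] + period
    ifelse(j <= n, j, period + 1 - j)
  }
}

# 2-D correlation of a single-channel matrix with a centered odd-sized kernel
filter2_boundary <- function(x, kern, boundary = "reflect") {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  ri <- extend_index(nrow(x), kr, boundary)
  ci <- extend_index(ncol(x), kc, boundary)
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(nrow(kern))) {
    for (b in seq_len(ncol(kern))) {
      w <- kern[a, b]
      if (w == 0) next
      out <- out + w * x[ri[seq_len(nrow(x)) + (a - 1L)],
                         ci[seq_len(ncol(x)) + (b - 1L)], drop = FALSE]
    }
  }
  out
}

# separable 1-D correlation along rows and columns
filter_sep_boundary <- function(x, k1d, boundary = "reflect") {
  r <- (length(k1d) - 1L) %/% 2L
  # along columns (vertical)
  ri <- extend_index(nrow(x), r, boundary)
  tmp <- matrix(0, nrow(x), ncol(x))
  for (a in seq_along(k1d)) {
    tmp <- tmp + k1d[a] * x[ri[seq_len(nrow(x)) + (a - 1L)], , drop = FALSE]
  }
  # along rows (horizontal)
  ci <- extend_index(ncol(x), r, boundary)
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_along(k1d)) {
    out <- out + k1d[a] * tmp[, ci[seq_len(ncol(x)) + (a - 1L)], drop = FALSE]
  }
  out
}

#' Gaussian low-pass filter
#'
#' Separable Gaussian blur with a kernel truncated at 4 standard deviations
#' and renormalized to unit sum, so constants are preserved exactly.
#'
#' @param img image matrix or array.
#' @param sigma standard deviation in pixels (> 0).
#' @param boundary `"reflect"` or `"circular"` extension.
#' @return blurred image, same shape as the input.
#' @export
gaussian_blur <- function(img, sigma, boundary = "reflect") {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  apply_channels(img, function(ch) filter_sep_boundary(ch, k, boundary))
}

#' Raw Laplacian response of an image
#'
#' Discrete second-derivative response: correlation with the configured 3 x 3
#' Laplacian stencil under the configured boundary extension. The response is
#' returned unclipped and may be negative.
#'
#' @param img image matrix or array on the `[0, 255]` scale.
#' @param cfg a [sharpen_config()].
#' @return response of the same shape as `img`.
#' @export
laplacian_response <- function(img, cfg = sharpen_config("laplacian")) {
  validate_raster(img)
  kern <- laplacian_kernel(cfg$kernel_variant)
  apply_channels(img, function(ch) filter2_boundary(ch, kern, cfg$boundary))
}

#' Laplacian edge sharpening
#'
#' Subtracts the scaled Laplacian response from the image
#' (`clip(img - gain * response)`); because the stencils have negative
#' centers, the subtraction adds edge contrast.
#'
#' @inheritParams laplacian_response
#' @return sharpened image clipped to `[0, 255]`.
#' @export
sharpen_laplacian <- function(img, cfg = sharpen_config("laplacian")) {
  clip_to_range(img - cfg$gain * laplacian_response(img, cfg))
}

#' Unsharp masking
#'
#' Adds back a scaled high-pass residual: the correction signal is the image
#' minus its Gaussian-blurred copy, and the output is
#' `clip(img + gain * (img - blur(img, sigma)))`. The image size is
#' unchanged.
#'
#' @inheritParams laplacian_response
#' @return sharpened image clipped to `[0, 255]`.
#' @export
sharpen_unsharp <- function(img, cfg = sharpen_config("unsharp")) {
  validate_raster(img)
  corr <- img - gaussian_blur(img, cfg$sigma, cfg$boundary)
  clip_to_range(img + cfg$gain * corr)
}

#' Two-dimensional discrete Fourier transform
#'
#' Unnormalized forward transform with negative exponent, so the (1,1)
#' coefficient (frequency (0,0)) is the sum of all pixels — the DC component
#' corresponding to average brightness.
#'
#' @param img single-channel image matrix (split RGB channels first).
#' @return an object of class `spectral_image` with complex `coefficients`.
#' @export
dft2 <- function(img) {
  if (!is.matrix(img)) {
    stop("dft2 operates on single-channel matrices; split RGB channels first",
         call. = FALSE)
  }
  structure(list(coefficients = stats::fft(img)), class = "spectral_image")
}

#' Inverse two-dimensional discrete Fourier transform
#'
#' Normalized inverse (division by M*N); returns the real part, which for
#' spectra of real images carries an imaginary residue below 1e-9 of the real
#' magnitude.
#'
#' @param spec a `spectral_image` (or bare complex matrix).
#' @return numeric matrix.
#' @export
idft2 <- function(spec) {
  co <- if (inherits(spec, "spectral_image")) spec$coefficients else spec
  Re(stats::fft(co, inverse = TRUE)) / length(co)
}

# frequency response of the 3x3 Laplacian stencil on an M x N periodic grid
laplacian_transfer <- function(M, N, variant) {
  kern <- laplacian_kernel(variant)
  K <- matrix(0, M, N)
  for (dr in -1:1) {
    for (dc in -1:1) {
      r <- (dr %% M) + 1L
      c <- (dc %% N) + 1L
      K[r, c] <- K[r, c] + kern[dr + 2L, dc + 2L]
    }
  }
  stats::fft(K)
}

# radial frequency-distance window: 0 at DC, 1 at the Nyquist corner
radial_emphasis_window <- function(M, N) {
  fu <- 0:(M - 1); fu <- pmin(fu, M - fu)
  fv <- 0:(N - 1); fv <- pmin(fv, N - fv)
  r <- sqrt(outer(fu^2, fv^2, "+"))
  r / sqrt(floor(M / 2)^2 + floor(N / 2)^2)
}

#' Hybrid Laplacian + DFT sharpening
#'
#' Cross-domain sharpener: the Laplacian second-derivative mask is applied as
#' a transfer function in the Fourier domain (via the convolution theorem),
#' optionally re-weighted by a radial high-frequency emphasis window
#' `W(u, v) = r(u, v) / r_max` (0 at DC, 1 at the Nyquist corner), and the
#' inverse-transformed correction is subtracted from the image. With
#' `emphasis = FALSE` the result is identical to [sharpen_laplacian()] under
#' circular boundary extension.
#'
#' @inheritParams laplacian_response
#' @return sharpened image clipped to `[0, 255]`.
#' @export
sharpen_lf_dft <- function(img, cfg = sharpen_config("lf_dft")) {
  validate_raster(img)
  one <- function(ch) {
    M <- nrow(ch); N <- ncol(ch)
    S <- stats::fft(ch)
    C <- S * laplacian_transfer(M, N, cfg$kernel_variant)
    if (cfg$emphasis) C <- C * radial_emphasis_window(M, N)
    corr <- Re(stats::fft(C, inverse = TRUE)) / (M * N)
    clip_to_range(ch - cfg$gain * corr)
  }
  apply_channels(img, one)
}

#' Apply the configured sharpener to an image
#'
#' Dispatches on `cfg$method`; `"none"` returns the image unchanged.
#'
#' @inheritParams laplacian_response
#' @return (possibly) sharpened image.
#' @export
sharpen_image <- function(img, cfg) {
  stopifnot(inherits(cfg, "sharpen_config"))
  switch(cfg$method,
    none      = img,
    laplacian = sharpen_laplacian(img, cfg),
    unsharp   = sharpen_unsharp(img, cfg),
    lf_dft    = sharpen_lf_dft(img, cfg)
  )
}
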