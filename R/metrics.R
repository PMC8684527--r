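# Full-reference quality metrics for fused images. All metrics operate on the
# [0, 255] float scale with G = 256 grey levels (peak signal G - 1 = 255).
# RGB inputs are pooled over all elements, except ERGAS (per-band aggregation)
# and entropy (computed on the luma channel).

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images have different shapes: ",
         paste(dim(a), collapse = " x "), " vs ",
         paste(dim(b), collapse = " x "), call. = FALSE)
  }
}

#' Root mean square error
#'
#' `sqrt(mean((reference - test)^2))` over all elements.
#'
#' @param reference true (all-in-focus) image.
#' @param test fused or degraded image of the same shape.
#' @return nonnegative scalar; 0 iff the images are equal.
#' @export
rmse <- function(reference, test) {
  check_same_shape(reference, test)
  sqrt(mean((reference - test)^2))
}

#' Percentage fit error
#'
#' Norm of the reference-vs-test difference normalized by image norms, times
#' 100. The default (`variant = "printed"`) is the two-term form
#' `(||Iz - If|| / ||Iz|| + ||Iz - If|| / ||If||) * 100` (Frobenius norms);
#' `variant = "conventional"` is the usual single-term
#' `||Iz - If|| / ||Iz|| * 100`.
#'
#' @inheritParams rmse
#' @param variant `"printed"` (two-term) or `"conventional"` (single-term).
#' @return nonnegative scalar; 0 iff the images are equal.
#' @export
pfe <- function(reference, test, variant = c("printed", "conventional")) {
  variant <- match.arg(variant)
  check_same_shape(reference, test)
  nz <- sqrt(sum(reference^2))
  nf <- sqrt(sum(test^2))
  if (nz == 0) stop("PFE undefined: reference image is all zero", call. = FALSE)
  nd <- sqrt(sum((reference - test)^2))
  if (variant == "conventional") return(100 * nd / nz)
  if (nf == 0) stop("PFE undefined: test image is all zero", call. = FALSE)
  100 * (nd / nz + nd / nf)
}

#' Mean absolute error of a fused image against both sources
#'
#' Two-term form: the mean absolute deviation of the fused image from the
#' first input plus the mean absolute deviation from the second input.
#' `variant = "conventional"` uses only the first input as the reference.
#'
#' @param source_a,source_b the two input images.
#' @param fused the fused image.
#' @param variant `"printed"` (two-term sum) or `"conventional"`.
#' @return nonnegative scalar; the printed form is 0 iff `fused` equals both
#'   inputs.
#' @export
mae_fusion <- function(source_a, source_b, fused,
                       variant = c("printed", "conventional")) {
  variant <- match.arg(variant)
  check_same_shape(source_a, fused)
  check_same_shape(source_b, fused)
  m1 <- mean(abs(source_a - fused))
  if (variant == "conventional") return(m1)
  m1 + mean(abs(source_b - fused))
}

#' Shannon entropy of an 8-bit image histogram
#'
#' Pixels are rounded to the 256 integer grey levels on `[0, 255]` (values
#' outside are clipped); the entropy of the resulting histogram is returned
#' in bits (log base 2), so the result lies in `[0, 8]`. RGB images are
#' reduced to luma first.
#'
#' @param img image matrix or array.
#' @return entropy in bits.
#' @export
entropy <- function(img) {
  if (!is.matrix(img)) img <- rgb_to_gray(img)
  g <- round(clip_to_range(img))
  p <- tabulate(as.integer(g) + 1L, nbins = GREY_LEVELS)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(sum(reference^2) / sum((reference - test)^2))`; `Inf` when the
#' images are equal.
#'
#' @inheritParams rmse
#' @return SNR in dB.
#' @export
snr <- function(reference, test) {
  check_same_shape(reference, test)
  sig <- sum(reference^2)
  if (sig == 0) stop("SNR undefined: reference image is all zero", call. = FALSE)
  err <- sum((reference - test)^2)
  if (err == 0) return(Inf)
  10 * log10(sig / err)
}

#' Peak signal-to-noise ratio in decibels
#'
#' The default (`variant = "conventional"`) is
#' `10 * log10((G - 1)^2 / MSE)` with `G - 1 = 255` — the scale on which
#' typical fused-image values of 26–44 dB live. `variant = "printed"` is the
#' literal `20 * log10(G^2 / MSE)` form with `G = 256`. `Inf` when the images
#' are equal.
#'
#' @inheritParams rmse
#' @param variant `"conventional"` or `"printed"`.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, variant = c("conventional", "printed")) {
  variant <- match.arg(variant)
  check_same_shape(reference, test)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  if (variant == "conventional") {
    10 * log10((GREY_LEVELS - 1)^2 / mse)
  } else {
    20 * log10(GREY_LEVELS^2 / mse)
  }
}

#' Energy-normalized correlation
#'
#' `2 * sum(Iz * Ip) / (sum(Iz^2) + sum(Ip^2))` — an energy-normalized
#' similarity (not Pearson correlation): 1 iff the images are identical, 0
#' when they are orthogonal, and within `[0, 1]` for nonnegative images.
#'
#' @inheritParams rmse
#' @return similarity in `[-1, 1]`.
#' @export
cc <- function(reference, test) {
  check_same_shape(reference, test)
  cz <- sum(reference^2)
  cp <- sum(test^2)
  if (cz + cp == 0) {
    stop("correlation undefined: both images are all zero", call. = FALSE)
  }
  2 * sum(reference * test) / (cz + cp)
}

#' ERGAS (relative dimensionless global error of synthesis)
#'
#' `100 * scale_ratio * sqrt(mean_i(RMSE_i^2 / mean_i^2))` over the `n`
#' bands, where `RMSE_i` and `mean_i` are the per-band RMSE and per-band
#' reference mean. `scale_ratio` is the resolution ratio `dh/dl`, 1 for
#' same-resolution multifocus fusion.
#'
#' @inheritParams rmse
#' @param scale_ratio resolution ratio (default 1).
#' @return nonnegative scalar; 0 iff the images are equal.
#' @export
ergas <- function(reference, test, scale_ratio = 1) {
  check_same_shape(reference, test)
  band <- function(k) {
    if (is.matrix(reference)) list(r = reference, t = test)
    else list(r = reference[, , k], t = test[, , k])
  }
  nb <- n_channels(reference)
  terms <- vapply(seq_len(nb), function(k) {
    bk <- band(k)
    mu <- mean(bk$r)
    if (mu == 0) {
      stop("ERGAS undefined: reference band ", k, " has zero mean",
           call. = FALSE)
    }
    mean((bk$r - bk$t)^2) / mu^2
  }, numeric(1))
  100 * scale_ratio * sqrt(mean(terms))
}

#' Compute the full eight-metric quality report
#'
#' RMSE, PFE, SNR, PSNR, CC and ERGAS compare the fused image against the
#' reference (true all-in-focus) image; MAE is the two-term deviation of the
#' fused image from the two sources; entropy is that of the fused image
#' itself.
#'
#' @param source_a,source_b the two multifocus inputs.
#' @param fused the fused result.
#' @param reference the true all-in-focus image.
#' @param psnr_variant,pfe_variant,mae_variant formula variants, see
#'   [psnr()], [pfe()], [mae_fusion()].
#' @param ergas_ratio ERGAS resolution ratio (default 1).
#' @return an object of class `quality_report`: a named list of the eight
#'   metric values plus `variant_flags`.
#' @export
evaluate_all <- function(source_a, source_b, fused, reference,
                         psnr_variant = "conventional",
                         pfe_variant = "printed",
                         mae_variant = "printed",
                         ergas_ratio = 1) {
  check_same_shape(fused, reference)
  rep <- list(
    rmse    = rmse(reference, fused),
    pfe     = pfe(reference, fused, pfe_variant),
    mae     = mae_fusion(source_a, source_b, fused, mae_variant),
    entropy = entropy(fused),
    snr     = snr(reference, fused),
    psnr    = psnr(reference, fused, psnr_variant),
    cc      = cc(reference, fused),
    ergas   = ergas(reference, fused, ergas_ratio),
    variant_flags = list(psnr = psnr_variant, pfe = pfe_variant,
                         mae = mae_variant, ergas_ratio = ergas_ratio)
  )
  structure(rep, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  for (m in c("rmse", "pfe", "mae", "entropy", "snr", "psnr", "cc", "ergas")) {
    cat(sprintf("  %-8s %.6g\n", m, x[[m]]))
  }
  invisible(x)
}

#' @export
as.data.frame.quality_report <- function(x, ...) {
  data.frame(rmse = x$rmse, pfe = x$pfe, mae = x$mae, entropy = x$entropy,
             snr = x$snr, psnr = x$psnr, cc = x$cc, ergas = x$ergas)
}
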