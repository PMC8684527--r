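# Fusion back-ends: pixelwise average and minimum in the spatial domain, and
# per-subband coefficient fusion in the DWT/SWT domains.

#' Fusion configuration
#'
#' @param method `"average"`, `"minimum"`, `"dwt"` or `"swt"`.
#' @param wavelet wavelet name for the transform methods (default `"db2"`).
#' @param levels decomposition depth (default 2).
#' @param approx_rule rule for the approximation subband: `"mean"` or
#'   `"max_abs"`.
#' @param detail_rule rule for the detail subbands: `"max_abs"` (select the
#'   coefficient of larger magnitude, the standard multifocus choice) or
#'   `"mean"`.
#' @return an object of class `fuse_config`.
#' @export
fuse_config <- function(method = c("swt", "dwt", "average", "minimum"),
                        wavelet = "db2", levels = 2L,
                        approx_rule = c("mean", "max_abs"),
                        detail_rule = c("max_abs", "mean")) {
  method <- match.arg(method)
  approx_rule <- match.arg(approx_rule)
  detail_rule <- match.arg(detail_rule)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  wavelet_filters(wavelet)  # validates the name
  structure(list(method = method, wavelet = wavelet, levels = levels,
                 approx_rule = approx_rule, detail_rule = detail_rule),
            class = "fuse_config")
}

#' Pixelwise average fusion
#'
#' @param pair an [validate_pair()] `image_pair`.
#' @return fused image (arithmetic mean of the two sources).
#' @export
fuse_average <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  (pair$source_a + pair$source_b) / 2
}

#' Pixelwise minimum fusion
#'
#' @inheritParams fuse_average
#' @return fused image (pointwise minimum of the two sources).
#' @export
fuse_minimum <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  pmin(pair$source_a, pair$source_b)
}

# elementwise combination rules; ties under max_abs go to `a`
combine_rule <- function(a, b, rule) {
  switch(rule,
    mean    = (a + b) / 2,
    max_abs = ifelse(abs(b) > abs(a), b, a),
    stop("unknown fusion rule '", rule, "'", call. = FALSE)
  )
}

#' Fuse two structurally identical wavelet pyramids
#'
#' The approximation subbands are combined by `cfg$approx_rule` and every
#' detail subband elementwise by `cfg$detail_rule`; `"max_abs"` selects the
#' coefficient of larger magnitude, with ties broken toward `pyr_a`.
#'
#' @param pyr_a,pyr_b `wavelet_pyramid`s with identical transform, wavelet,
#'   depth and extents.
#' @param cfg a [fuse_config()].
#' @return fused `wavelet_pyramid`.
#' @export
fuse_coefficients <- function(pyr_a, pyr_b, cfg = fuse_config()) {
  stopifnot(inherits(pyr_a, "wavelet_pyramid"),
            inherits(pyr_b, "wavelet_pyramid"))
  same <- identical(pyr_a$transform, pyr_b$transform) &&
    identical(pyr_a$wavelet, pyr_b$wavelet) &&
    identical(pyr_a$levels, pyr_b$levels) &&
    identical(dim(pyr_a$approx), dim(pyr_b$approx)) &&
    identical(pyr_a$orig_dim, pyr_b$orig_dim)
  if (!same) {
    stop("cannot fuse structurally different pyramids ",
         "(transform/wavelet/levels/extents must match)", call. = FALSE)
  }
  out <- pyr_a
  out$approx <- combine_rule(pyr_a$approx, pyr_b$approx, cfg$approx_rule)
  for (j in seq_len(pyr_a$levels)) {
    for (s in c("h", "v", "d")) {
      out$details[[j]][[s]] <- combine_rule(pyr_a$details[[j]][[s]],
                                            pyr_b$details[[j]][[s]],
                                            cfg$detail_rule)
    }
  }
  out
}

# wavelet-domain fusion of one channel pair
fuse_wavelet_channel <- function(a, b, cfg) {
  pa <- decompose(a, cfg$method, cfg$wavelet, cfg$levels)
  pb <- decompose(b, cfg$method, cfg$wavelet, cfg$levels)
  reconstruct(fuse_coefficients(pa, pb, cfg))
}

#' Sharpen-then-fuse pipeline
#'
#' Applies the configured sharpener to both source images, then fuses them
#' with the configured method (per channel for RGB; the wavelet path is
#' decompose both, fuse coefficients, reconstruct, clip). The method and
#' sharpener combination is recorded in the `"provenance"` attribute of the
#' result.
#'
#' @param pair an `image_pair`.
#' @param fuse_cfg a [fuse_config()].
#' @param sharpen_cfg a [sharpen_config()]; `method = "none"` skips
#'   preprocessing.
#' @return fused image clipped to `[0, 255]`, with attribute `"provenance"`.
#' @export
fuse <- function(pair, fuse_cfg = fuse_config(),
                 sharpen_cfg = sharpen_config("none")) {
  stopifnot(inherits(pair, "image_pair"), inherits(fuse_cfg, "fuse_config"))
  a <- sharpen_image(pair$source_a, sharpen_cfg)
  b <- sharpen_image(pair$source_b, sharpen_cfg)
  sp <- validate_pair(a, b)
  fused <- switch(fuse_cfg$method,
    average = fuse_average(sp),
    minimum = fuse_minimum(sp),
    dwt     = ,
    swt     = {
      ch <- function(x, y) fuse_wavelet_channel(x, y, fuse_cfg)
      if (is.matrix(a)) ch(a, b) else {
        out <- a
        for (k in seq_len(dim(a)[3])) out[, , k] <- ch(a[, , k], b[, , k])
        out
      }
    }
  )
  fused <- clip_to_range(fused)
  attr(fused, "provenance") <- list(
    method = fuse_cfg$method, sharpener = sharpen_cfg$method,
    wavelet = fuse_cfg$wavelet, levels = fuse_cfg$levels,
    approx_rule = fuse_cfg$approx_rule, detail_rule = fuse_cfg$detail_rule,
    gain = sharpen_cfg$gain, sigma = sharpen_cfg$sigma,
    kernel_variant = sharpen_cfg$kernel_variant,
    boundary = sharpen_cfg$boundary, emphasis = sharpen_cfg$emphasis)
  fused
}
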