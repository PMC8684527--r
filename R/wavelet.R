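# Orthonormal wavelet filter banks used by the fusion back-ends.
#
# Both transforms use periodic (circular) signal extension, under which the
# orthonormal Daubechies filters give exact perfect reconstruction:
#   - DWT: decimated analysis a[n] = sum_k g[k] x[2n + k] (indices mod length),
#     synthesis scatters with the same filters — the orthonormal-basis
#     expansion on Z_N, so reconstruction is exact for even N.
#   - SWT: undecimated ("a trous") analysis with filters upsampled by 2^(j-1),
#     computed as circular correlation via the FFT. Because the analysis pair
#     satisfies |G(w)|^2 + |H(w)|^2 = 2 at every frequency, the circular
#     inverse (synthesis transfer functions, divided by 2 per dimension) is
#     exact and the transform is exactly shift-equivariant.

#' Orthonormal Daubechies wavelet filter pair
#'
#' @param name `"haar"` (alias `"db1"`), `"db2"` or `"db4"`.
#' @return list with components `lo` (scaling filter, sum `sqrt(2)`) and
#'   `hi` (quadrature-mirror wavelet filter).
#' @export
wavelet_filters <- function(name = "db2") {
  s3 <- sqrt(3)
  lo <- switch(name,
    haar = ,
    db1  = c(1, 1) / sqrt(2),
    db2  = c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)),
    db4  = c(0.230377813308855230, 0.714846570552541500,
             0.630880767929590400, -0.027983769416983850,
             -0.187034811718881140, 0.030841381835986965,
             0.032883011666982945, -0.010597401784997278),
    stop("unsupported wavelet '", name, "' (use haar/db1, db2, db4)",
         call. = FALSE)
  )
  L <- length(lo)
  hi <- (-1)^(0:(L - 1)) * rev(lo)
  list(lo = lo, hi = hi, name = if (name == "haar") "db1" else name)
}

# ---- decimated DWT (periodized) ---------------------------------------------

# one analysis step along the row index; x must have an even number of rows
dwt_cols <- function(x, f) {
  n <- nrow(x)
  half <- n %/% 2L
  a <- matrix(0, half, ncol(x))
  d <- a
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(f$lo)) {
    idx <- ((base + (k - 1L)) %% n) + 1L
    xs <- x[idx, , drop = FALSE]
    a <- a + f$lo[k] * xs
    d <- d + f$hi[k] * xs
  }
  list(a = a, d = d)
}

# one synthesis step along the row index (inverse of dwt_cols)
idwt_cols <- function(a, d, f) {
  half <- nrow(a)
  n <- 2L * half
  x <- matrix(0, n, ncol(a))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(f$lo)) {
    idx <- ((base + (k - 1L)) %% n) + 1L
    x[idx, ] <- x[idx, ] + f$lo[k] * a + f$hi[k] * d
  }
  x
}

# duplicate last row/column so both extents are even; returns padded matrix
pad_even <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}

# single-level 2-D decimated step; returns subbands and the pre-pad input dim
dwt2_once <- function(x, f) {
  in_dim <- dim(x)
  x <- pad_even(x)
  cs <- dwt_cols(x, f)                      # along the row index
  ra <- dwt_cols(t(cs$a), f)                # along the column index
  rd <- dwt_cols(t(cs$d), f)
  list(a = t(ra$a), v = t(ra$d), h = t(rd$a), d = t(rd$d), in_dim = in_dim)
}

idwt2_once <- function(a, h, v, d, f, in_dim) {
  ca <- t(idwt_cols(t(a), t(v), f))
  cd <- t(idwt_cols(t(h), t(d), f))
  x <- idwt_cols(ca, cd, f)
  x[seq_len(in_dim[1]), seq_len(in_dim[2]), drop = FALSE]
}

# ---- undecimated SWT (FFT-based circular filtering) -------------------------

# DFT of filter g upsampled by factor s on a length-n circle
upsampled_transfer <- function(g, s, n) {
  v <- numeric(n)
  for (k in seq_along(g)) {
    i <- (((k - 1L) * s) %% n) + 1L
    v[i] <- v[i] + g[k]
  }
  stats::fft(v)
}

swt2_once <- function(x, f, step) {
  M <- nrow(x); N <- ncol(x)
  gc_lo <- upsampled_transfer(f$lo, step, M)
  gc_hi <- upsampled_transfer(f$hi, step, M)
  gr_lo <- upsampled_transfer(f$lo, step, N)
  gr_hi <- upsampled_transfer(f$hi, step, N)
  Fx <- stats::fft(x)
  band <- function(gc, gr) {
    Re(stats::fft(Fx * outer(Conj(gc), Conj(gr)), inverse = TRUE)) / (M * N)
  }
  list(a = band(gc_lo, gr_lo), h = band(gc_hi, gr_lo),
       v = band(gc_lo, gr_hi), d = band(gc_hi, gr_hi))
}

iswt2_once <- function(a, h, v, d, f, step) {
  M <- nrow(a); N <- ncol(a)
  gc_lo <- upsampled_transfer(f$lo, step, M)
  gc_hi <- upsampled_transfer(f$hi, step, M)
  gr_lo <- upsampled_transfer(f$lo, step, N)
  gr_hi <- upsampled_transfer(f$hi, step, N)
  S <- stats::fft(a) * outer(gc_lo, gr_lo) +
       stats::fft(h) * outer(gc_hi, gr_lo) +
       stats::fft(v) * outer(gc_lo, gr_hi) +
       stats::fft(d) * outer(gc_hi, gr_hi)
  Re(stats::fft(S, inverse = TRUE)) / (M * N) / 4
}

# symmetric padding of bottom/right edges up to target extents
pad_to <- function(x, M, N) {
  if (nrow(x) < M) {
    extra <- extend_index(nrow(x), M - nrow(x), "reflect")
    extra <- extra[(length(extra) - (M - nrow(x)) + 1L):length(extra)]
    x <- rbind(x, x[extra, , drop = FALSE])
  }
  if (ncol(x) < N) {
    extra <- extend_index(ncol(x), N - ncol(x), "reflect")
    extra <- extra[(length(extra) - (N - ncol(x)) + 1L):length(extra)]
    x <- cbind(x, x[, extra, drop = FALSE])
  }
  x
}

# ---- pyramid API ------------------------------------------------------------

#' Multilevel wavelet decomposition of a single-channel image
#'
#' Decomposes an image into a coarsest-level approximation and per-level
#' horizontal/vertical/diagonal detail subbands, with either the decimated
#' DWT (level-l subbands of extent `ceiling(M/2^l)`) or the undecimated,
#' shift-equivariant SWT (all subbands keep the full image extent; the image
#' is symmetrically padded to a multiple of `2^levels` first and cropped
#' again on reconstruction).
#'
#' @param img single-channel image matrix.
#' @param transform `"dwt"` or `"swt"`.
#' @param wavelet wavelet name, see [wavelet_filters()].
#' @param levels decomposition depth (>= 1).
#' @return an object of class `wavelet_pyramid`: fields `approx` and
#'   `details` (a list, finest level first, each with `h`, `v`, `d`).
#' @export
decompose <- function(img, transform = c("dwt", "swt"),
                      wavelet = "db2", levels = 2L) {
  transform <- match.arg(transform)
  if (!is.matrix(img)) {
    stop("decompose operates on single-channel matrices", call. = FALSE)
  }
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  if (2^levels > min(dim(img))) {
    stop("image of extent ", nrow(img), " x ", ncol(img),
         " is too small for ", levels, " decomposition levels",
         " (needs min extent >= ", 2^levels, ")", call. = FALSE)
  }
  f <- wavelet_filters(wavelet)
  orig_dim <- dim(img)
  details <- vector("list", levels)
  if (transform == "dwt") {
    a <- img
    level_dims <- vector("list", levels)
    for (j in seq_len(levels)) {
      st <- dwt2_once(a, f)
      details[[j]] <- list(h = st$h, v = st$v, d = st$d)
      level_dims[[j]] <- st$in_dim
      a <- st$a
    }
    out <- list(approx = a, details = details, level_dims = level_dims)
  } else {
    m <- 2^levels
    padded <- c(ceiling(orig_dim[1] / m), ceiling(orig_dim[2] / m)) * m
    a <- pad_to(img, padded[1], padded[2])
    for (j in seq_len(levels)) {
      st <- swt2_once(a, f, step = 2L^(j - 1L))
      details[[j]] <- list(h = st$h, v = st$v, d = st$d)
      a <- st$a
    }
    out <- list(approx = a, details = details, level_dims = NULL)
  }
  structure(c(out, list(transform = transform, wavelet = f$name,
                        levels = levels, orig_dim = orig_dim,
                        extension_mode = "periodic")),
            class = "wavelet_pyramid")
}

#' Reconstruct an image from a wavelet pyramid
#'
#' Inverse of [decompose()]; padding added during decomposition is removed so
#' the output extent equals the original image extent. Reconstruction is
#' exact (perfect reconstruction) to well below 1e-8.
#'
#' @param pyr a `wavelet_pyramid`.
#' @return single-channel image matrix.
#' @export
reconstruct <- function(pyr) {
  stopifnot(inherits(pyr, "wavelet_pyramid"))
  f <- wavelet_filters(pyr$wavelet)
  a <- pyr$approx
  if (pyr$transform == "dwt") {
    for (j in rev(seq_len(pyr$levels))) {
      dl <- pyr$details[[j]]
      a <- idwt2_once(a, dl$h, dl$v, dl$d, f, pyr$level_dims[[j]])
    }
    a
  } else {
    for (j in rev(seq_len(pyr$levels))) {
      dl <- pyr$details[[j]]
      a <- iswt2_once(a, dl$h, dl$v, dl$d, f, step = 2L^(j - 1L))
    }
    a[seq_len(pyr$orig_dim[1]), seq_len(pyr$orig_dim[2]), drop = FALSE]
  }
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat("<wavelet_pyramid> ", toupper(x$transform), " ", x$wavelet,
      ", ", x$levels, " level(s), image ",
      x$orig_dim[1], " x ", x$orig_dim[2], "\n", sep = "")
  invisible(x)
}
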