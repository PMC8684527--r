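#' @keywords internal
"_PACKAGE"

# Numeric conventions used throughout the package:
#   - images are plain numeric matrices (grayscale, M x N) or M x N x 3 arrays
#     (RGB), floating point on the nominal [0, 255] scale;
#   - indexing is (row, col), row 1 at the top;
#   - G = 256 grey levels, so the peak signal is G - 1 = 255.

GREY_LEVELS <- 256

#' Clip image values to the representable intensity range
#'
#' @param x numeric matrix or array.
#' @param lo,hi range bounds (defaults 0 and 255).
#' @return `x` with all values forced into `[lo, hi]`.
#' @export
clip_to_range <- function(x, lo = 0, hi = 255) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

#' Number of channels of an image
#'
#' @param img image matrix or array.
#' @return 1 for a grayscale matrix, 3 for an RGB array.
#' @export
n_channels <- function(img) {
  if (is.matrix(img)) 1L else dim(img)[3]
}

#' Validate an image against the package's raster conventions
#'
#' Checks that `img` is a numeric matrix (grayscale) or an M x N x 3 array
#' (RGB), with finite values and spatial extent of at least 8 x 8 (the
#' minimum the wavelet stages can decompose meaningfully).
#'
#' @param img candidate image.
#' @param what label used in error messages.
#' @return `img`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_raster <- function(img, what = "image") {
  if (!is.numeric(img)) {
    stop(what, " must be numeric", call. = FALSE)
  }
  d <- dim(img)
  ok <- (is.matrix(img) && length(d) == 2L) ||
    (is.array(img) && length(d) == 3L && d[3] == 3L)
  if (!ok) {
    stop(what, " must be an M x N matrix or an M x N x 3 array", call. = FALSE)
  }
  if (d[1] < 8L || d[2] < 8L) {
    stop(what, " must be at least 8 x 8, got ", d[1], " x ", d[2],
         call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(img)
}

#' Convert an RGB image to grayscale luma
#'
#' Uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img M x N x 3 array on the `[0, 255]` scale.
#' @return M x N matrix.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Load an image file as a float raster on the [0, 255] scale
#'
#' Supports PNG, TIFF and JPEG. 8- and 16-bit inputs are both rescaled to the
#' nominal `[0, 255]` scale. An alpha channel, if present, is dropped with a
#' warning. RGB images can be collapsed to luma with `force_gray`.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @param force_gray collapse RGB input to grayscale via BT.601 luma weights.
#' @return numeric matrix (grayscale) or M x N x 3 array (RGB).
#' @export
load_image <- function(path, force_gray = FALSE) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png  = png::readPNG,
    tif  = tiff::readTIFF,
    tiff = tiff::readTIFF,
    jpg  = jpeg::readJPEG,
    jpeg = jpeg::readJPEG,
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  raw <- tryCatch(reader(path), error = function(e) {
    stop("cannot read image ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  d <- dim(raw)
  if (length(d) == 3L) {
    if (d[3] == 4L) {
      warning("dropping alpha channel of ", path)
      raw <- raw[, , 1:3, drop = FALSE]
    } else if (d[3] == 2L) {
      warning("dropping alpha channel of ", path)
      raw <- raw[, , 1, drop = TRUE]
    } else if (d[3] == 1L) {
      raw <- raw[, , 1, drop = TRUE]
    }
  }
  img <- raw * 255
  if (force_gray && !is.matrix(img)) img <- rgb_to_gray(img)
  validate_raster(img, path)
  img
}

#' Save an image as an 8-bit PNG or TIFF
#'
#' Values are clipped to `[0, 255]` and rounded half-to-even before
#' quantization, so `load_image(save_image(x))` equals
#' `clip_to_range(round(x))` exactly.
#'
#' @param img image matrix or array on the `[0, 255]` scale.
#' @param path destination path; extension selects the codec (.png/.tif/.tiff).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  validate_raster(img)
  q <- round(clip_to_range(img)) / 255
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png  = png::writePNG(q, path),
      tif  = tiff::writeTIFF(q, path, bits.per.sample = 8L),
      tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
      stop("unsupported output format '", ext, "' (use .png/.tif/.tiff)",
           call. = FALSE)
    )
    TRUE
  }, error = function(e) {
    stop("cannot write image ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Pair two registered multifocus source images
#'
#' The two sources must have identical spatial extent and channel count;
#' mixing, say, a 512 x 512 frame with a 520 x 520 frame, or grayscale with
#' RGB, is refused.
#'
#' @param a,b images (matrix or M x N x 3 array) on the `[0, 255]` scale.
#' @return an object of class `image_pair` with elements `source_a`,
#'   `source_b`.
#' @export
validate_pair <- function(a, b) {
  validate_raster(a, "source_a")
  validate_raster(b, "source_b")
  da <- dim(a)
  db <- dim(b)
  if (length(da) != length(db) || !all(da == db)) {
    stop("cannot pair images of different shape: ",
         paste(da, collapse = " x "), " vs ", paste(db, collapse = " x "),
         call. = FALSE)
  }
  if (n_channels(a) != n_channels(b)) {
    stop("cannot pair images with different channel counts", call. = FALSE)
  }
  structure(list(source_a = a, source_b = b), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  d <- dim(x$source_a)
  cat("<image_pair> ", d[1], " x ", d[2], ", ",
      n_channels(x$source_a), " channel(s)\n", sep = "")
  invisible(x)
}

# apply fun(channel_matrix) to each channel; reassembles RGB arrays
apply_channels <- function(img, fun) {
  if (is.matrix(img)) return(fun(img))
  out <- img
  for (k in seq_len(dim(img)[3])) out[, , k] <- fun(img[, , k])
  out
}
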