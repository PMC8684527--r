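# Seeded synthetic multifocus scenes: a sharp ground-truth image plus two
# complementary region-wise defocused sources, standing in for multifocus
# benchmark photographs (512 x 512 grayscale and 520 x 520 RGB sets) that are
# not publicly deposited. All operations are pure functions of
# (preset, seed, parameters); the global RNG state is left untouched.

preset_dims <- function(preset) {
  switch(preset,
    gray512 = list(dim = c(512L, 512L), channels = 1L),
    rgb520  = list(dim = c(520L, 520L), channels = 3L),
    tiny64  = list(dim = c(64L, 64L), channels = 1L),
    stop("unknown preset '", preset, "' (gray512, rgb520, tiny64)",
         call. = FALSE)
  )
}

# run expr with a local RNG seeded at `seed`, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# paint one random shape onto each channel of `img` (list of matrices)
paint_shapes <- function(channels, M, N, n_shapes) {
  rows <- matrix(seq_len(M), M, N)
  cols <- matrix(seq_len(N), M, N, byrow = TRUE)
  for (i in seq_len(n_shapes)) {
    type <- sample(c("rect", "ellipse", "grating"), 1L)
    vals <- stats::runif(length(channels), 20, 235)
    if (type == "rect") {
      r0 <- sample.int(M - 8L, 1L); r1 <- min(M, r0 + sample.int(M %/% 3L, 1L))
      c0 <- sample.int(N - 8L, 1L); c1 <- min(N, c0 + sample.int(N %/% 3L, 1L))
      for (k in seq_along(channels)) {
        channels[[k]][r0:r1, c0:c1] <- vals[k]
      }
    } else if (type == "ellipse") {
      rc <- stats::runif(1, M * 0.1, M * 0.9)
      cc <- stats::runif(1, N * 0.1, N * 0.9)
      ra <- stats::runif(1, M / 20, M / 5)
      rb <- stats::runif(1, N / 20, N / 5)
      inside <- ((rows - rc) / ra)^2 + ((cols - cc) / rb)^2 <= 1
      for (k in seq_along(channels)) {
        channels[[k]][inside] <- vals[k]
      }
    } else {
      # oriented sinusoidal grating confined to a random rectangular band
      r0 <- sample.int(M - 8L, 1L); r1 <- min(M, r0 + sample.int(M %/% 2L, 1L))
      c0 <- sample.int(N - 8L, 1L); c1 <- min(N, c0 + sample.int(N %/% 2L, 1L))
      th <- stats::runif(1, 0, pi)
      freq <- stats::runif(1, 0.15, 0.7)
      phase <- stats::runif(1, 0, 2 * pi)
      sub <- sin(freq * (rows[r0:r1, c0:c1] * cos(th) +
                           cols[r0:r1, c0:c1] * sin(th)) + phase)
      for (k in seq_along(channels)) {
        base <- stats::runif(1, 70, 180)
        amp <- stats::runif(1, 40, 75)
        channels[[k]][r0:r1, c0:c1] <- base + amp * sub
      }
    }
  }
  channels
}

#' Generate a deterministic sharp ground-truth scene
#'
#' Produces a synthetic all-in-focus image with high-frequency content
#' everywhere: a smooth background gradient, random rectangles, ellipses and
#' oriented sinusoidal gratings (at least one grating per image quadrant,
#' guaranteeing sharp detail in both halves), plus low-amplitude Gaussian
#' texture noise. The same `(preset, seed)` always reproduces the identical
#' image.
#'
#' @param preset `"gray512"` (512 x 512 grayscale), `"rgb520"`
#'   (520 x 520 RGB), or `"tiny64"` (64 x 64 grayscale, for fast tests).
#' @param seed integer RNG seed.
#' @return image matrix or array on the `[0, 255]` scale.
#' @export
generate_ground_truth <- function(preset = "gray512", seed = 42L) {
  pd <- preset_dims(preset)
  M <- pd$dim[1]; N <- pd$dim[2]
  with_local_seed(seed, {
    base <- outer(seq(60, 110, length.out = M), seq(0, 40, length.out = N), "+")
    channels <- lapply(seq_len(pd$channels), function(k) {
      base * stats::runif(1, 0.8, 1.2)
    })
    n_shapes <- if (preset == "tiny64") 6L else 18L
    channels <- paint_shapes(channels, M, N, n_shapes)
    # one grating per quadrant so every half carries high-frequency detail
    rows <- matrix(seq_len(M), M, N)
    cols <- matrix(seq_len(N), M, N, byrow = TRUE)
    qr <- list(1:(M %/% 2), (M %/% 2 + 1):M)
    qc <- list(1:(N %/% 2), (N %/% 2 + 1):N)
    for (a in 1:2) {
      for (b in 1:2) {
        th <- stats::runif(1, 0, pi)
        freq <- stats::runif(1, 0.25, 0.8)
        sub <- sin(freq * (rows[qr[[a]], qc[[b]]] * cos(th) +
                             cols[qr[[a]], qc[[b]]] * sin(th)))
        sel_r <- qr[[a]][seq_len(length(qr[[a]]) %/% 2)]
        sel_c <- qc[[b]][seq_len(length(qc[[b]]) %/% 2)]
        for (k in seq_along(channels)) {
          channels[[k]][sel_r, sel_c] <-
            channels[[k]][sel_r, sel_c] + 45 * sub[seq_along(sel_r),
                                                   seq_along(sel_c)]
        }
      }
    }
    noise <- matrix(stats::rnorm(M * N, sd = 2.5), M, N)
    img <- if (pd$channels == 1L) {
      clip_to_range(channels[[1]] + noise)
    } else {
      arr <- array(0, c(M, N, 3L))
      for (k in 1:3) arr[, , k] <- clip_to_range(channels[[k]] + noise)
      arr
    }
    img
  })
}

#' Build a focus mask
#'
#' Returns an M x N matrix of weights in `[0, 1]`; 1 marks the region where
#' source A is in focus. `transition_width = 0` gives a hard 0/1 partition;
#' a positive width gives a linear ramp of that width (pixels) across the
#' boundary. For the half geometries `mask + flip(mask) = 1` everywhere.
#'
#' @param shape integer vector `c(M, N)`.
#' @param geometry `"half_vertical"` (left half in focus),
#'   `"half_horizontal"` (top half), or `"disc"` (centered disc of radius
#'   `min(M, N)/4`).
#' @param transition_width ramp width in pixels (>= 0).
#' @return M x N numeric matrix in `[0, 1]`.
#' @export
make_focus_mask <- function(shape,
                            geometry = c("half_vertical", "half_horizontal",
                                         "disc"),
                            transition_width = 0) {
  geometry <- match.arg(geometry)
  stopifnot(transition_width >= 0)
  M <- shape[1]; N <- shape[2]
  ramp <- function(signed_dist) {
    if (transition_width == 0) as.numeric(signed_dist > 0)
    else pmin(1, pmax(0, 0.5 + signed_dist / transition_width))
  }
  if (geometry == "half_vertical") {
    cut <- N / 2 + 0.5
    matrix(ramp(cut - seq_len(N)), M, N, byrow = TRUE)
  } else if (geometry == "half_horizontal") {
    cut <- M / 2 + 0.5
    matrix(ramp(cut - seq_len(M)), M, N)
  } else {
    r0 <- (M + 1) / 2; c0 <- (N + 1) / 2
    rad <- min(M, N) / 4
    d <- sqrt(outer((seq_len(M) - r0)^2, (seq_len(N) - c0)^2, "+"))
    matrix(ramp(rad - d), M, N)
  }
}

#' Simulate complementary defocus from a sharp scene
#'
#' Models defocus as fixed-sigma Gaussian blur blended by the focus mask:
#' with `B = gaussian_blur(gt, blur_sigma)`, source A is
#' `mask * gt + (1 - mask) * B` and source B is the complement, so
#' `source_a + source_b = gt + B` pointwise (exact, pre-quantization).
#'
#' @param gt sharp ground-truth image.
#' @param mask focus mask from [make_focus_mask()] (1 = A in focus).
#' @param blur_sigma Gaussian blur sigma in pixels (> 0).
#' @return an `image_pair` of the two defocused sources.
#' @export
defocus_pair <- function(gt, mask, blur_sigma = 3) {
  stopifnot(blur_sigma > 0)
  validate_raster(gt)
  B <- gaussian_blur(gt, blur_sigma)
  blend <- function(x, y) apply_channels_pairwise(x, y, mask)
  a <- blend(gt, B)
  b <- blend(B, gt)
  validate_pair(a, b)
}

# mask * x + (1 - mask) * y, per channel
apply_channels_pairwise <- function(x, y, mask) {
  if (is.matrix(x)) return(mask * x + (1 - mask) * y)
  out <- x
  for (k in seq_len(dim(x)[3])) {
    out[, , k] <- mask * x[, , k] + (1 - mask) * y[, , k]
  }
  out
}

#' Generate a complete synthetic multifocus fixture
#'
#' Composes [generate_ground_truth()], [make_focus_mask()] and
#' [defocus_pair()] into a provenance-carrying scene record.
#'
#' @inheritParams generate_ground_truth
#' @param blur_sigma defocus blur sigma in pixels (default 3).
#' @param geometry focus-mask geometry, see [make_focus_mask()].
#' @param transition_width mask ramp width in pixels (default 0, hard split).
#' @return an object of class `synth_scene`: `ground_truth`, `focus_mask`,
#'   `pair`, and the generating parameters.
#' @export
make_fixture <- function(preset = "gray512", seed = 42L, blur_sigma = 3,
                         geometry = "half_vertical", transition_width = 0) {
  gt <- generate_ground_truth(preset, seed)
  d <- if (is.matrix(gt)) dim(gt) else dim(gt)[1:2]
  mask <- make_focus_mask(d, geometry, transition_width)
  pair <- defocus_pair(gt, mask, blur_sigma)
  structure(list(ground_truth = gt, focus_mask = mask, pair = pair,
                 blur_sigma = blur_sigma, transition_width = transition_width,
                 seed = as.integer(seed), preset = preset,
                 geometry = geometry),
            class = "synth_scene")
}

#' @export
print.synth_scene <- function(x, ...) {
  d <- if (is.matrix(x$ground_truth)) dim(x$ground_truth)
       else dim(x$ground_truth)[1:2]
  cat("<synth_scene> preset ", x$preset, " (", d[1], " x ", d[2],
      "), seed ", x$seed, ", blur sigma ", x$blur_sigma,
      ", geometry ", x$geometry, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic scene to disk as a PNG triplet plus JSON sidecar
#'
#' Writes `source_a.png`, `source_b.png`, `ground_truth.png` and
#' `scene.json` (seed and parameters) into `dir`.
#'
#' @param scene a `synth_scene`.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(scene, dir) {
  stopifnot(inherits(scene, "synth_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_image(scene$pair$source_a, file.path(dir, "source_a.png"))
  save_image(scene$pair$source_b, file.path(dir, "source_b.png"))
  save_image(scene$ground_truth, file.path(dir, "ground_truth.png"))
  meta <- list(preset = scene$preset, seed = scene$seed,
               blur_sigma = scene$blur_sigma, geometry = scene$geometry,
               transition_width = scene$transition_width)
  jsonlite::write_json(meta, file.path(dir, "scene.json"), auto_unbox = TRUE)
  invisible(dir)
}
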