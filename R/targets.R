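#' Generate synthetic target images
#'
#' Renders reproducible character-like glyphs and binary patterns that stand
#' in for the handwritten-character training corpus and the custom
#' letter/pattern test set used in holographic display work: no download is
#' required and every image is a pure function of `(spec, seed)`.
#'
#' Kinds:
#' \describe{
#'   \item{`"glyphs"`}{2-4 random thick strokes (polylines and arcs), the
#'     stroke-and-curve statistics of handwritten characters.}
#'   \item{`"binary"`}{composites of 2-5 filled rectangles, disks, rings and
#'     dot clusters (smiley-like patterns).}
#'   \item{`"disks"`}{a single filled disk of random size and position.}
#'   \item{`"mixed"`}{kind drawn at random per image.}
#' }
#' Images are lightly smoothed (separable Gaussian, `blur_sigma` px) so the
#' targets are grayscale rather than hard binary, then max-normalized to
#' `[0, 1]`. Every image is guaranteed at least 1% nonzero pixels.
#'
#' @param count number of images (>= 1).
#' @param size image side in pixels (>= 16); images are square.
#' @param kind target family, see Details.
#' @param seed integer seed; the same `(spec, seed)` always yields the same
#'   images.
#' @param stroke_frac glyph stroke width as a fraction of the image side.
#' @param blur_sigma Gaussian smoothing sigma in pixels (0 disables).
#' @return a list of `size x size` numeric matrices in `[0, 1]`.
#' @export
generate_targets <- function(count, size = 64L,
                             kind = c("glyphs", "binary", "disks", "mixed"),
                             seed = NULL, stroke_frac = 0.045,
                             blur_sigma = 0.7) {
  kind <- match.arg(kind)
  count <- as.integer(count); size <- as.integer(size)
  if (count < 1L) stop("count must be >= 1")
  if (size < 16L) stop("size must be >= 16")
  with_seed_if(seed, {
    lapply(seq_len(count), function(i) {
      k <- if (kind == "mixed")
        sample(c("glyphs", "binary", "disks"), 1) else kind
      img <- switch(k,
        glyphs = draw_glyph(size, stroke_frac),
        binary = draw_binary_pattern(size),
        disks = draw_disk_target(size))
      img <- finish_target(img, size, blur_sigma)
      img
    })
  })
}

# pixel-centre coordinate grids in [0, 1]
unit_grid <- function(size) {
  s <- (seq_len(size) - 0.5) / size
  list(x = matrix(s, size, size, byrow = TRUE), y = matrix(s, size, size))
}

# distance-to-segment rasterization of a thick polyline
paint_polyline <- function(img, pts, width, g) {
  r2 <- (width / 2)^2
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((g$x - a[1]) * ab[1] +
                                                  (g$y - a[2]) * ab[2]) / len2))
    d2 <- (g$x - (a[1] + t * ab[1]))^2 + (g$y - (a[2] + t * ab[2]))^2
    img[d2 <= r2] <- 1
  }
  img
}

arc_points <- function(center, radius, a0, a1, n = 24L) {
  th <- seq(a0, a1, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

draw_glyph <- function(size, stroke_frac) {
  g <- unit_grid(size)
  img <- matrix(0, size, size)
  n_strokes <- sample(2:4, 1)
  for (s in seq_len(n_strokes)) {
    if (runif(1) < 0.35) {
      pts <- arc_points(runif(2, 0.3, 0.7), runif(1, 0.1, 0.3),
                        runif(1, 0, 2 * pi), runif(1, 0, 2 * pi) +
                          runif(1, pi / 2, 1.5 * pi))
    } else {
      npts <- sample(3:4, 1)
      pts <- cbind(runif(npts, 0.15, 0.85), runif(npts, 0.15, 0.85))
    }
    img <- paint_polyline(img, pts, runif(1, 0.8, 1.3) * stroke_frac, g)
  }
  img
}

draw_binary_pattern <- function(size) {
  g <- unit_grid(size)
  img <- matrix(0, size, size)
  for (s in seq_len(sample(2:5, 1))) {
    shape <- sample(c("rect", "disk", "ring", "dots"), 1)
    c0 <- runif(2, 0.25, 0.75)
    if (shape == "rect") {
      hw <- runif(2, 0.05, 0.2)
      img[abs(g$x - c0[1]) <= hw[1] & abs(g$y - c0[2]) <= hw[2]] <- 1
    } else if (shape == "disk") {
      r <- runif(1, 0.05, 0.18)
      img[(g$x - c0[1])^2 + (g$y - c0[2])^2 <= r^2] <- 1
    } else if (shape == "ring") {
      r <- runif(1, 0.1, 0.25); w <- runif(1, 0.25, 0.5) * r
      d2 <- (g$x - c0[1])^2 + (g$y - c0[2])^2
      img[d2 <= r^2 & d2 >= (r - w)^2] <- 1
    } else {
      for (k in seq_len(sample(2:4, 1))) {
        ck <- c0 + runif(2, -0.15, 0.15)
        r <- runif(1, 0.02, 0.05)
        img[(g$x - ck[1])^2 + (g$y - ck[2])^2 <= r^2] <- 1
      }
    }
  }
  img
}

draw_disk_target <- function(size) {
  g <- unit_grid(size)
  img <- matrix(0, size, size)
  c0 <- runif(2, 0.3, 0.7); r <- runif(1, 0.1, 0.25)
  img[(g$x - c0[1])^2 + (g$y - c0[2])^2 <= r^2] <- 1
  img
}

finish_target <- function(img, size, blur_sigma) {
  if (sum(img > 0) < 0.01 * size^2) {
    g <- unit_grid(size)
    img[(g$x - 0.5)^2 + (g$y - 0.5)^2 <= 0.15^2] <- 1
  }
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img
}

# separable Gaussian smoothing with edge-renormalized taps
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (d in (-r):r) {
      rows <- pmin(pmax(seq_len(n) + d, 1L), n)
      out <- out + k[d + r + 1] * m[rows, , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Preprocess a target image to the working and modulator grids
#'
#' Resizes an arbitrary grayscale image to the working resolution (bilinear),
#' zero-pads it centred to the modulator resolution, and max-normalizes it.
#' Defaults follow the package's desk profile (48 x 48 work area inside a
#' 64 x 64 grid); the full-scale profile (512 x 512 padded to 1920 x 1080)
#' is a matter of passing those sizes.
#'
#' @param image numeric matrix with at least one positive pixel.
#' @param work_size target size of the resized image, `(rows, cols)` or a
#'   scalar.
#' @param slm_size final padded size, `(rows, cols)` or a scalar; must be
#'   >= `work_size` in both dimensions.
#' @return a numeric `slm_size` matrix in `[0, 1]`.
#' @export
preprocess_target <- function(image, work_size = c(48L, 48L),
                              slm_size = c(64L, 64L)) {
  if (!is.matrix(image) || !any(image > 0))
    stop("image must be a matrix with at least one positive pixel")
  if (length(work_size) == 1L) work_size <- rep(work_size, 2)
  if (length(slm_size) == 1L) slm_size <- rep(slm_size, 2)
  work_size <- as.integer(work_size); slm_size <- as.integer(slm_size)
  if (any(work_size > slm_size))
    stop("work_size must not exceed slm_size")
  resized <- EBImage::resize(image, w = work_size[1], h = work_size[2])
  resized <- pmax(matrix(as.numeric(resized), work_size[1], work_size[2]), 0)
  out <- matrix(0, slm_size[1], slm_size[2])
  off <- (slm_size - work_size) %/% 2L
  out[off[1] + seq_len(work_size[1]), off[2] + seq_len(work_size[2])] <- resized
  out / max(out)
}
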