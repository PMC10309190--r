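# shared internal helpers

# Distance (um) of every pixel center from a binary mask (TRUE inside).
# Mask pixels get 0. Euclidean distance between pixel centers, scaled by
# pixel_size; corner pixels therefore use true Euclidean distance rather
# than a structuring-element approximation.
dist_from_mask <- function(mask, pixel_size) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(!mask), nrow = nrow(mask))
  d <- EBImage::distmap(m)
  as.matrix(d) * pixel_size
}

# Pixel-center coordinate grids in um (top-left pixel center at (0, 0)).
# Row index = y, column index = x.
pixel_grid <- function(shape, pixel_size) {
  y <- (seq_len(shape[1]) - 1) * pixel_size
  x <- (seq_len(shape[2]) - 1) * pixel_size
  list(y = matrix(y, nrow = shape[1], ncol = shape[2]),
       x = matrix(x, nrow = shape[1], ncol = shape[2], byrow = TRUE))
}

# Radial distance (um) of every pixel center from a point (x0, y0) in um.
radial_dist <- function(shape, pixel_size, x0, y0) {
  g <- pixel_grid(shape, pixel_size)
  sqrt((g$x - x0)^2 + (g$y - y0)^2)
}

# Run expr with a locally seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Additive Gaussian noise (sd in absolute intensity units) plus optional
# Poisson shot noise; negative intensities are clipped to 0.
add_noise <- function(img, gaussian_sd = 0, shot = FALSE) {
  out <- img
  if (shot) out[] <- stats::rpois(length(out), lambda = pmax(out, 0))
  if (gaussian_sd > 0) out <- out + stats::rnorm(length(out), sd = gaussian_sd)
  pmax(out, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
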