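#' Segmentation parameters
#'
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param min_area Minimum object area in um^2 (default 1.5, the size
#'   filter that keeps engulfed yeast and rejects debris).
#' @param fill_holes Fill internal holes of each object.
#' @return A `pf_seg_params`.
#' @export
seg_params <- function(threshold = "otsu", min_area = 1.5, fill_holes = TRUE) {
  if (min_area <= 0) stop("min_area must be > 0")
  if (!(identical(threshold, "otsu") || is.numeric(threshold))) {
    stop("threshold must be \"otsu\" or a numeric value")
  }
  structure(list(threshold = threshold, min_area = min_area,
                 fill_holes = fill_holes), class = "pf_seg_params")
}

# compact mask: linear pixel indices + image dim
new_mask <- function(idx, dim) structure(as.integer(idx), dim_hw = as.integer(dim))

mask_matrix <- function(mask) {
  d <- attr(mask, "dim_hw")
  m <- matrix(FALSE, d[1], d[2])
  m[as.integer(mask)] <- TRUE
  m
}

#' Segment engulfed particles in one grayscale frame
#'
#' Thresholds the particle (yeast) channel, optionally fills holes,
#' labels connected components and keeps objects at least `min_area` um^2.
#' Centroids are reported in um from the top-left pixel center (0-based
#' pixel convention); areas are pixel counts times `pixel_size^2`.
#'
#' @param image Numeric matrix (one frame, one channel).
#' @param pixel_size um per pixel (> 0).
#' @param params A [seg_params()].
#' @return Tibble of detections: `label`, `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity`, and a `mask` list-column of compact pixel-index
#'   masks. Zero rows for a blank/constant image.
#' @export
segment_particles <- function(image, pixel_size, params = seg_params()) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop("image must be a finite-valued numeric matrix")
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  stopifnot(inherits(params, "pf_seg_params"))
  empty <- tibble::tibble(label = integer(), x_um = numeric(),
                          y_um = numeric(), area_um2 = numeric(),
                          mean_intensity = numeric(), mask = list())
  rng <- range(image)
  if (identical(params$threshold, "otsu")) {
    if (diff(rng) == 0) return(empty)  # constant image: nothing to segment
    th <- rng[1] + EBImage::otsu((image - rng[1]) / diff(rng),
                                 range = c(0, 1)) * diff(rng)
  } else {
    th <- params$threshold
  }
  bin <- image > th
  if (!any(bin)) return(empty)
  if (params$fill_holes) bin <- EBImage::fillHull(bin * 1) > 0
  lab <- EBImage::bwlabel(bin * 1)
  labs <- sort(unique(lab[lab > 0]))
  min_px <- params$min_area / pixel_size^2
  rows <- lapply(labs, function(l) {
    idx <- which(lab == l)
    if (length(idx) < min_px) return(NULL)
    rc <- arrayInd(idx, dim(image))
    tibble::tibble(
      label = as.integer(l),
      x_um = mean(rc[, 2] - 1) * pixel_size,
      y_um = mean(rc[, 1] - 1) * pixel_size,
      area_um2 = length(idx) * pixel_size^2,
      mean_intensity = mean(image[idx]),
      mask = list(new_mask(idx, dim(image))))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}
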