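#' Detect membrane-coated beads from their equatorial rings
#'
#' Beads imaged at the equator appear as bright circles in the membrane
#' dye channel. The channel is thresholded, connected components are
#' labeled, and each component is accepted as a bead when its pixels form
#' a thin circle: center = component centroid, radius = mean pixel
#' distance to the centroid, with the radial spread bounded by the ring
#' thickness (touching/overlapping beads merge into one non-circular
#' component and are rejected).
#'
#' @param membrane Membrane-channel matrix.
#' @param pixel_size um per pixel.
#' @param radius_bounds Accepted radius range (um); default 4–6 for
#'   10-um beads.
#' @param ring_thickness_um Measurement ring thickness (um); also the
#'   circularity tolerance on the radial spread.
#' @return Tibble of `bead`, `x_um`, `y_um`, `radius_um`, `radial_sd_um`;
#'   zero rows (with a warning) when no circles are found. Rejected
#'   components are counted in the `n_rejected` attribute.
#' @export
segment_bead_rings <- function(membrane, pixel_size, radius_bounds = c(4, 6),
                               ring_thickness_um = 0.6) {
  det <- segment_particles(membrane, pixel_size,
                           seg_params(min_area = pi * radius_bounds[1] *
                                        ring_thickness_um / 2,
                                      fill_holes = FALSE))
  n_rejected <- 0L
  rows <- list()
  for (i in seq_len(nrow(det))) {
    m <- mask_matrix(det$mask[[i]])
    rc <- which(m, arr.ind = TRUE)
    cy <- mean(rc[, 1] - 1) * pixel_size
    cx <- mean(rc[, 2] - 1) * pixel_size
    rr <- sqrt(((rc[, 1] - 1) * pixel_size - cy)^2 +
                 ((rc[, 2] - 1) * pixel_size - cx)^2)
    r <- mean(rr)
    if (r >= radius_bounds[1] && r <= radius_bounds[2] &&
        stats::sd(rr) <= ring_thickness_um) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        x_um = cx, y_um = cy, radius_um = r, radial_sd_um = stats::sd(rr))
    } else {
      n_rejected <- n_rejected + 1L
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warning("no bead circles found")
    out <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          radius_um = numeric(), radial_sd_um = numeric())
  }
  out <- dplyr::mutate(out, bead = dplyr::row_number(), .before = 1)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Measure probe fluorescence around detected beads
#'
#' Mean probe intensity over an annulus of `ring_thickness_um` centered
#' on each detected circle, with the per-field background (median
#' off-bead intensity) subtracted.
#'
#' @param probe Probe-channel matrix (same field as the detections).
#' @param detections Tibble from [segment_bead_rings()].
#' @param pixel_size um per pixel.
#' @param ring_thickness_um Annulus thickness (um).
#' @return Tibble: `bead`, `intensity` (background-subtracted),
#'   `background`, `n_pixels`.
#' @export
measure_bead_probe <- function(probe, detections, pixel_size,
                               ring_thickness_um = 0.6) {
  shape <- dim(probe)
  off <- matrix(TRUE, shape[1], shape[2])
  rings <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    rho <- radial_dist(shape, pixel_size, d$x_um, d$y_um)
    rings[[i]] <- abs(rho - d$radius_um) <= ring_thickness_um / 2
    off <- off & rho > d$radius_um + ring_thickness_um
  }
  bg <- stats::median(probe[off])
  purrr::map_dfr(seq_len(nrow(detections)), function(i) {
    tibble::tibble(bead = detections$bead[i],
                   intensity = mean(probe[rings[[i]]]) - bg,
                   background = bg, n_pixels = sum(rings[[i]]))
  })
}

one_site <- function(conc, kd, bmax, nonspecific) {
  nonspecific + bmax * conc / (kd + conc)
}

fit_one_site <- function(df) {
  means <- tapply(df$intensity, df$conc_nM, mean)
  concs <- as.numeric(names(means))
  b0 <- max(means) - min(means)
  ns0 <- max(min(means), 0)
  half <- min(means) + b0 / 2
  kd0 <- concs[which.min(abs(means - half))]
  kd0 <- max(kd0, min(concs[concs > 0], 1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ nonspecific + bmax * conc_nM / (kd + conc_nM),
      data = df, start = list(kd = kd0, bmax = b0, nonspecific = ns0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("one-site fit did not converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  list(kd = co["kd", "Estimate"], bmax = co["bmax", "Estimate"],
       nonspecific = co["nonspecific", "Estimate"],
       kd_se = co["kd", "Std. Error"], bmax_se = co["bmax", "Std. Error"],
       residual_norm = sqrt(sum(stats::residuals(fit)^2)))
}

#' Fit a one-site saturation binding curve
#'
#' Nonlinear least squares of
#' `I(c) = nonspecific + bmax * c / (kd + c)` to per-bead titration data.
#' With an `experiment` column and more than one experiment, each
#' experiment is fit separately and the apparent Kd is reported as the
#' mean with its SD across experiments; otherwise a pooled fit is
#' bootstrapped over beads for the error.
#'
#' @param points Tibble with `conc_nM` and `intensity` (one row per
#'   bead), optionally `experiment`.
#' @param n_boot Bootstrap resamples for the pooled-fit error.
#' @param seed Bootstrap seed.
#' @return A `pf_binding_fit`: `kd` (nM), `kd_error`, `bmax`,
#'   `nonspecific`, `residual_norm`, `no_binding` (bmax not
#'   distinguishable from 0), `per_experiment` tibble, `data`.
#' @export
fit_binding <- function(points, n_boot = 1000L, seed = 1L) {
  stopifnot(all(c("conc_nM", "intensity") %in% names(points)))
  concs <- unique(points$conc_nM)
  if (length(concs) < 2) stop("concentrations are all equal; cannot fit")
  if (length(concs) < 4) {
    warning("fewer than 4 distinct concentrations; Kd poorly constrained")
  }
  per_exp <- NULL
  if ("experiment" %in% names(points) &&
      length(unique(points$experiment)) > 1) {
    per_exp <- points |>
      dplyr::group_by(.data$experiment) |>
      dplyr::group_modify(~tibble::as_tibble(fit_one_site(.x)[
        c("kd", "bmax", "nonspecific", "bmax_se", "residual_norm")])) |>
      dplyr::ungroup()
    kd <- mean(per_exp$kd); kd_error <- stats::sd(per_exp$kd)
    bmax <- mean(per_exp$bmax); nonspecific <- mean(per_exp$nonspecific)
    bmax_se <- mean(per_exp$bmax_se)
    residual_norm <- sqrt(sum(per_exp$residual_norm^2))
  } else {
    f <- fit_one_site(points)
    kd <- f$kd; bmax <- f$bmax; nonspecific <- f$nonspecific
    bmax_se <- f$bmax_se; residual_norm <- f$residual_norm
    kd_error <- if (f$residual_norm < 1e-10) 0 else {
      boots <- with_seed(seed, {
        vapply(seq_len(n_boot), function(b) {
          idx <- sample(nrow(points), replace = TRUE)
          tryCatch(fit_one_site(points[idx, ])$kd, error = function(e)
            NA_real_)
        }, 0)
      })
      stats::sd(boots, na.rm = TRUE)
    }
  }
  if (length(unique(points$conc_nM)) >= 4 &&
      (kd < min(concs[concs > 0]) / 2 || kd > 2 * max(concs))) {
    warning("fitted Kd lies outside the titrated concentration range")
  }
  structure(list(kd = kd, kd_error = kd_error, bmax = bmax,
                 nonspecific = nonspecific, residual_norm = residual_norm,
                 no_binding = bmax <= 2 * bmax_se,
                 per_experiment = per_exp, data = points,
                 model = "one-site saturation"),
            class = "pf_binding_fit")
}

#' @export
print.pf_binding_fit <- function(x, ...) {
  cat(sprintf("<pf_binding_fit> apparent Kd = %.4g +/- %.3g nM, Bmax = %.4g, NS = %.4g%s\n",
              x$kd, x$kd_error, x$bmax, x$nonspecific,
              if (x$no_binding) " [no binding detected]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pf_binding_fit <- function(x, ...) {
  tibble::tibble(term = c("kd", "bmax", "nonspecific"),
                 estimate = c(x$kd, x$bmax, x$nonspecific),
                 std.error = c(x$kd_error, NA, NA))
}

#' @export
glance.pf_binding_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, kd_error = x$kd_error, bmax = x$bmax,
                 nonspecific = x$nonspecific,
                 residual_norm = x$residual_norm,
                 no_binding = x$no_binding,
                 n_experiments = if (is.null(x$per_experiment)) 1L else
                   nrow(x$per_experiment))
}

#' Lipid selectivity ratio from an intensity panel
#'
#' Ratio of the named lipid's mean (background-subtracted) intensity to
#' the largest mean among all other lipids. Negative means are clipped to
#' a small positive floor (logged via message) so the ratio stays
#' defined.
#'
#' @param panel Tidy tibble `(lipid, intensity)`, e.g. from
#'   [generate_lipid_panel()].
#' @param selective_lipid Lipid whose preference is quantified; defaults
#'   to the panel's `selective_lipid` attribute.
#' @return A `pf_selectivity`: `per_lipid` means, `ratio`,
#'   `selective_lipid`.
#' @export
selectivity_ratio <- function(panel,
                              selective_lipid =
                                attr(panel, "selective_lipid")) {
  stopifnot(all(c("lipid", "intensity") %in% names(panel)))
  if (length(unique(panel$lipid)) < 2) {
    stop("selectivity requires at least 2 lipids")
  }
  if (is.null(selective_lipid) || !selective_lipid %in% panel$lipid) {
    stop("selective_lipid must name a lipid in the panel")
  }
  per <- panel |>
    dplyr::group_by(.data$lipid) |>
    dplyr::summarise(mean_intensity = mean(.data$intensity),
                     .groups = "drop")
  floor_val <- 1e-3 * max(abs(per$mean_intensity))
  if (any(per$mean_intensity < 0)) {
    message("negative lipid means clipped to floor ", signif(floor_val, 3))
    per$mean_intensity <- pmax(per$mean_intensity, floor_val)
  }
  others <- per$mean_intensity[per$lipid != selective_lipid]
  ratio <- per$mean_intensity[per$lipid == selective_lipid] / max(others)
  structure(list(per_lipid = per, ratio = ratio,
                 selective_lipid = selective_lipid),
            class = "pf_selectivity")
}

#' @export
print.pf_selectivity <- function(x, ...) {
  cat(sprintf("<pf_selectivity> %s preferred %.3g-fold over strongest other lipid\n",
              x$selective_lipid, x$ratio))
  invisible(x)
}

#' @export
tidy.pf_selectivity <- function(x, ...) x$per_lipid
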