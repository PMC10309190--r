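#' Ring-mask geometry around a segmented particle
#'
#' The particle perimeter is enlarged into two concentric rings: an inner
#' ring starting `inner_gap` um out (over the phagosomal membrane) and an
#' outer ring starting `outer_gap` um out (over bulk cytosol, the
#' background reference). Both rings are `thickness` um thick. Defaults
#' follow the measurement geometry used for the reporter movies:
#' 0.2 um inner enlargement, 0.85 um outer, ~0.35 um thickness.
#'
#' @param inner_gap,outer_gap Perimeter enlargements (um);
#'   `0 <= inner_gap`, and `inner_gap + thickness <= outer_gap` so the
#'   rings are disjoint.
#' @param thickness Ring thickness (um, > 0).
#' @param clip_tolerance Maximum fraction of a ring allowed to fall off
#'   the image before the frame is flagged unusable.
#' @return A `pf_ring_geometry`.
#' @export
ring_geometry <- function(inner_gap = 0.2, thickness = 0.35,
                          outer_gap = 0.85, clip_tolerance = 0.1) {
  if (!(inner_gap >= 0 && inner_gap < outer_gap)) {
    stop("require 0 <= inner_gap < outer_gap")
  }
  if (thickness <= 0) stop("thickness must be > 0")
  if (inner_gap + thickness > outer_gap) {
    stop("inner ring (inner_gap + thickness) overlaps the outer ring")
  }
  structure(list(inner_gap = inner_gap, thickness = thickness,
                 outer_gap = outer_gap, clip_tolerance = clip_tolerance),
            class = "pf_ring_geometry")
}

#' Build inner/outer ring masks around a particle mask
#'
#' Dilation by a physical distance `d` is defined as all pixels whose
#' center lies within Euclidean distance `d` of the particle mask
#' (distance-transform thresholding, so corners use true Euclidean
#' distance). The inner ring is `dilate(gap + thickness) \ dilate(gap)`;
#' the outer ring likewise with `outer_gap`. Both exclude the particle
#' itself and are disjoint by construction.
#'
#' @param particle_mask Logical matrix (or compact mask from
#'   [segment_particles()]).
#' @param geometry A [ring_geometry()].
#' @param pixel_size um per pixel.
#' @return List: `inner`, `outer` (logical matrices), `clipped_fraction`
#'   (estimated fraction of the outer ring lost at the image border), and
#'   `usable` (`FALSE` when clipping exceeds the geometry's tolerance).
#' @export
make_ring_masks <- function(particle_mask, geometry = ring_geometry(),
                            pixel_size) {
  stopifnot(inherits(geometry, "pf_ring_geometry"), pixel_size > 0)
  if (!is.matrix(particle_mask)) particle_mask <- mask_matrix(particle_mask)
  if (!any(particle_mask)) stop("particle mask is empty")
  g <- geometry
  pad <- as.integer(ceiling((g$outer_gap + g$thickness) / pixel_size)) + 2L
  d0 <- dim(particle_mask)
  padded <- matrix(FALSE, d0[1] + 2 * pad, d0[2] + 2 * pad)
  padded[pad + seq_len(d0[1]), pad + seq_len(d0[2])] <- particle_mask
  D <- dist_from_mask(padded, pixel_size)
  ring <- function(from, to) D > from & D <= to & !padded
  inner_p <- ring(g$inner_gap, g$inner_gap + g$thickness)
  outer_p <- ring(g$outer_gap, g$outer_gap + g$thickness)
  crop <- function(m) m[pad + seq_len(d0[1]), pad + seq_len(d0[2])]
  inner <- crop(inner_p); outer <- crop(outer_p)
  clipped <- 1 - (sum(inner) + sum(outer)) / (sum(inner_p) + sum(outer_p))
  list(inner = inner, outer = outer, clipped_fraction = clipped,
       usable = clipped <= g$clip_tolerance)
}

#' Measure ring intensities for tracked events
#'
#' For every usable frame of every event, measures the mean particle
#' (pHrodo proxy) intensity and the inner/outer ring means in each
#' reporter channel. Frames whose rings are clipped by the image border
#' beyond tolerance are excluded and counted in the `n_flagged` attribute.
#'
#' @param tl A `pf_timelapse` (or compatible list with `stack`,
#'   `channels`, `pixel_size`, `frame_interval`).
#' @param events Event tibble from [build_events()] with annotated
#'   `engulfment_frame`.
#' @param geometry A [ring_geometry()].
#' @param channels Reporter channel names; default every channel except
#'   `"particle"`.
#' @return Tibble: `event_id`, `frame`, `t_s` (relative to engulfment),
#'   `channel`, `particle_mean`, `inner_mean`, `outer_mean`, `n_inner`,
#'   `n_outer`.
#' @export
measure_event <- function(tl, events, geometry = ring_geometry(),
                          channels = setdiff(tl$channels, "particle")) {
  stopifnot(all(channels %in% tl$channels))
  if (nrow(events) == 0) stop("no events to measure")
  if (any(events$frame < 0) || any(events$frame >= dim(tl$stack)[4])) {
    stop("event frames fall outside the stack")
  }
  ch_idx <- match(channels, tl$channels)
  part_idx <- match("particle", tl$channels)
  out <- list(); n_flagged <- 0L
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    rings <- make_ring_masks(ev$mask[[1]], geometry, tl$pixel_size)
    if (!rings$usable) { n_flagged <- n_flagged + 1L; next }
    f <- ev$frame
    pmask <- mask_matrix(ev$mask[[1]])
    pmean <- if (!is.na(part_idx)) {
      mean(tl$stack[, , part_idx, f + 1L][pmask])
    } else NA_real_
    t_s <- (f - ev$engulfment_frame) * tl$frame_interval
    for (k in seq_along(channels)) {
      img <- tl$stack[, , ch_idx[k], f + 1L]
      out[[length(out) + 1L]] <- tibble::tibble(
        event_id = ev$event_id, frame = f, t_s = t_s,
        channel = channels[k], particle_mean = pmean,
        inner_mean = mean(img[rings$inner]),
        outer_mean = mean(img[rings$outer]),
        n_inner = sum(rings$inner), n_outer = sum(rings$outer))
    }
  }
  if (length(out) == 0) stop("event(s) entirely outside usable frames")
  res <- dplyr::bind_rows(out)
  attr(res, "n_flagged") <- n_flagged
  res
}

#' Background-normalized fold-enrichment traces
#'
#' Each frame's inner-ring mean is first normalized to the outer-ring
#' (cytosol background) mean; the resulting ratio is then referenced to
#' its value at the frame nearest to (at or before) `reference_time`,
#' giving fold-enrichment with value exactly 1 at the reference frame.
#' Division (rather than subtraction) by the background makes the trace
#' invariant to detector gain.
#'
#' @param measurements Tibble from [measure_event()].
#' @param reference_time Reference time (s relative to engulfment);
#'   default -10 s, i.e. just before engulfment.
#' @return Tibble: `event_id`, `channel`, `frame`, `t_s`,
#'   `fold_enrichment`.
#' @export
fold_enrichment <- function(measurements, reference_time = -10) {
  measurements |>
    dplyr::group_by(.data$event_id, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      pre <- df$t_s <= reference_time
      if (!any(pre)) {
        stop("no frame at or before the reference time (",
             reference_time, " s); annotate an earlier engulfment window")
      }
      ref <- which(pre)[which.max(df$t_s[pre])]
      ratio <- df$inner_mean / df$outer_mean
      tibble::tibble(frame = df$frame, t_s = df$t_s,
                     fold_enrichment = ratio / ratio[ref])
    }) |>
    dplyr::ungroup()
}

#' Cohort mean, SEM and per-timepoint tests across experiments
#'
#' Statistics follow the experiment-as-unit convention: traces are first
#' averaged within each independent experiment, then the mean and SEM are
#' taken across experiments (n = number of experiments, not events). With
#' exactly two conditions a two-sided unpaired (Welch) t-test is run at
#' every common timepoint; raw p-values are reported as in the source
#' assays, with a Holm-corrected column added as a labeled extension.
#'
#' @param traces Tibble with columns `condition`, `experiment`,
#'   `event_id`, `t_s`, `fold_enrichment` (e.g. from [fold_enrichment()]
#'   plus labels).
#' @param time_grid Common time grid (s); default inferred from the data
#'   (unique times snapped to the median frame interval). Trace times are
#'   resampled to the nearest grid point.
#' @return List: `summary` (condition, t_s, mean, sem, n_experiments) and
#'   `tests` (t_s, p_value, p_holm) or `NULL` when not two conditions.
#' @export
aggregate_cohort <- function(traces, time_grid = NULL) {
  stopifnot(all(c("condition", "experiment", "event_id", "t_s",
                  "fold_enrichment") %in% names(traces)))
  if (is.null(time_grid)) {
    ts <- sort(unique(traces$t_s))
    dt <- stats::median(diff(ts))
    time_grid <- seq(min(ts), max(ts), by = dt)
  }
  snap <- function(t) {
    vapply(t, function(x) time_grid[which.min(abs(time_grid - x))], 0)
  }
  by_exp <- traces |>
    dplyr::mutate(t_s = snap(.data$t_s)) |>
    dplyr::group_by(.data$condition, .data$experiment, .data$t_s) |>
    dplyr::summarise(exp_mean = mean(.data$fold_enrichment), .groups = "drop")
  summary <- by_exp |>
    dplyr::group_by(.data$condition, .data$t_s) |>
    dplyr::summarise(
      mean = mean(.data$exp_mean),
      n_experiments = dplyr::n(),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$exp_mean) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop")
  conds <- unique(by_exp$condition)
  tests <- NULL
  if (length(conds) == 2) {
    tests <- by_exp |>
      tidyr::pivot_wider(names_from = "condition", values_from = "exp_mean",
                         values_fn = list) |>
      dplyr::group_by(.data$t_s) |>
      dplyr::summarise(p_value = {
        a <- unlist(.data[[conds[1]]]); b <- unlist(.data[[conds[2]]])
        if (length(a) >= 2 && length(b) >= 2 &&
            (stats::sd(a) > 0 || stats::sd(b) > 0)) {
          stats::t.test(a, b)$p.value
        } else NA_real_
      }, .groups = "drop")
    tests$p_holm <- stats::p.adjust(tests$p_value, method = "holm")
  }
  list(summary = summary, tests = tests, by_experiment = by_exp)
}
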