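#' Positivity rule for binary reporter scoring
#'
#' Replaces manual positive/negative scoring with an explicit rule: an
#' object is reporter-positive while its fold-enrichment is at least
#' `threshold`, sustained for at least `min_consecutive_frames` frames.
#'
#' @param threshold Fold-enrichment cutoff (> 1; default 1.5).
#' @param min_consecutive_frames Frames the threshold must be held.
#' @return A `pf_positivity_rule`.
#' @export
positivity_rule <- function(threshold = 1.5, min_consecutive_frames = 2L) {
  if (threshold <= 1) stop("threshold must be > 1")
  structure(list(threshold = threshold,
                 min_consecutive_frames = as.integer(min_consecutive_frames)),
            class = "pf_positivity_rule")
}

#' Arrival, peak, departure and dwell from an enrichment trace
#'
#' Timings use the half-maximum convention: the half-max level is
#' `1 + (peak - 1) / 2`; arrival is the first upward crossing and
#' departure the last time above that level, both by linear interpolation
#' between frames. If the trace ends above half-max the departure is
#' right-censored at the last observed time. A trace whose peak never
#' reaches `min_peak` is scored never-positive (all timings `NA`).
#'
#' @param trace Tibble with `t_s` and `fold_enrichment` for one event and
#'   channel (>= 5 frames spanning pre- and post-engulfment).
#' @param min_peak Peak fold-enrichment below which the event is scored
#'   never-positive (default 1.5).
#' @return One-row tibble: `t_arrival`, `t_peak`, `t_departure`, `dwell`
#'   (s), `peak_value`, `censored`, `positive`.
#' @export
extract_timing <- function(trace, min_peak = 1.5) {
  stopifnot(all(c("t_s", "fold_enrichment") %in% names(trace)))
  if (nrow(trace) < 5) stop("trace must have at least 5 frames")
  tr <- dplyr::arrange(trace, .data$t_s)
  y <- tr$fold_enrichment; t <- tr$t_s
  peak_i <- which.max(y); peak <- y[peak_i]
  if (peak < min_peak) {
    return(tibble::tibble(t_arrival = NA_real_, t_peak = NA_real_,
                          t_departure = NA_real_, dwell = NA_real_,
                          peak_value = peak, censored = FALSE,
                          positive = FALSE))
  }
  half <- 1 + (peak - 1) / 2
  cross_up <- function(i) {
    t[i] + (half - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
  }
  above <- y >= half
  first_above <- which(above)[1]
  t_arrival <- if (first_above == 1) t[1] else cross_up(first_above - 1)
  last_above <- max(which(above))
  censored <- last_above == length(y)
  t_departure <- if (censored) t[length(t)] else {
    i <- last_above
    t[i] + (y[i] - half) / (y[i] - y[i + 1]) * (t[i + 1] - t[i])
  }
  tibble::tibble(t_arrival = t_arrival, t_peak = t[peak_i],
                 t_departure = t_departure, dwell = t_departure - t_arrival,
                 peak_value = peak, censored = censored, positive = TRUE)
}

#' Timing summaries for a whole cohort of traces
#'
#' @param traces Tibble of traces with `event_id` (and optionally
#'   `channel`, `condition`, `experiment`) plus `t_s`,
#'   `fold_enrichment`.
#' @inheritParams extract_timing
#' @return One row per event (and channel) with the [extract_timing()]
#'   columns and grouping labels carried through.
#' @export
extract_timings <- function(traces, min_peak = 1.5) {
  keys <- intersect(c("condition", "experiment", "event_id", "channel"),
                    names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~extract_timing(.x, min_peak = min_peak)) |>
    dplyr::ungroup()
}

#' Per-event positive intervals under a positivity rule
#'
#' Runs of frames with fold-enrichment at or above the rule's threshold,
#' lasting at least `min_consecutive_frames`, become positive intervals.
#'
#' @param traces Trace tibble (with `event_id`, `t_s`,
#'   `fold_enrichment`).
#' @param rule A [positivity_rule()].
#' @return Tibble: `event_id`, `start_s`, `end_s`, `censored` (interval
#'   still open at the last observed frame), `obs_end_s`.
#' @export
positive_intervals <- function(traces, rule = positivity_rule()) {
  traces |>
    dplyr::group_by(.data$event_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$t_s)
      pos <- df$fold_enrichment >= rule$threshold
      r <- rle(pos)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= rule$min_consecutive_frames
      if (!any(keep)) {
        return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                              censored = logical(),
                              obs_end_s = numeric()))
      }
      tibble::tibble(start_s = df$t_s[starts[keep]],
                     end_s = df$t_s[ends[keep]],
                     censored = ends[keep] == nrow(df),
                     obs_end_s = max(df$t_s))
    }) |>
    dplyr::ungroup()
}

#' Retention curve: proportion of events positive over time
#'
#' Bins time after engulfment and reports, per bin, the proportion of
#' events positive anywhere in that bin among events still under
#' observation (right-censoring respected: an event no longer filmed does
#' not enter the denominator).
#'
#' @param intervals Tibble from [positive_intervals()]; `obs_end_s` per
#'   event bounds its observation.
#' @param bin_width Bin width (s), default 60.
#' @param t_max Upper end of the last bin (s); default the latest
#'   observation end.
#' @param all_events Optional vector of event ids observed (so events
#'   with no positive interval still count in denominators); defaults to
#'   the ids present in `intervals`.
#' @param obs_end Named vector or single value giving each event's
#'   observation end when `all_events` includes interval-free events.
#' @return Tibble: `bin_start_s`, `bin_end_s`, `n_observed`,
#'   `n_positive`, `proportion` (`NA` where no events observed).
#' @export
retention_curve <- function(intervals, bin_width = 60, t_max = NULL,
                            all_events = NULL, obs_end = NULL) {
  if (is.null(all_events)) all_events <- unique(intervals$event_id)
  if (length(all_events) == 0) stop("at least one event is required")
  ends <- stats::setNames(rep(NA_real_, length(all_events)), all_events)
  if (nrow(intervals) > 0) {
    e <- tapply(intervals$obs_end_s, intervals$event_id, max)
    ends[names(e)] <- e
  }
  if (!is.null(obs_end)) {
    if (length(obs_end) == 1 && is.null(names(obs_end))) {
      ends[is.na(ends)] <- obs_end
    } else ends[names(obs_end)] <- obs_end
  }
  if (anyNA(ends)) stop("observation end unknown for some events; ",
                        "supply obs_end")
  if (is.null(t_max)) t_max <- max(ends)
  bins <- seq(0, t_max, by = bin_width)
  if (bins[length(bins)] < t_max) bins <- c(bins, t_max)
  purrr::map_dfr(seq_len(length(bins) - 1L), function(b) {
    lo <- bins[b]; hi <- bins[b + 1L]
    observed <- names(ends)[ends > lo]
    pos <- unique(intervals$event_id[
      intervals$start_s < hi & intervals$end_s > lo])
    tibble::tibble(bin_start_s = lo, bin_end_s = hi,
                   n_observed = length(observed),
                   n_positive = sum(pos %in% observed),
                   proportion = if (length(observed) == 0) NA_real_ else
                     sum(pos %in% observed) / length(observed))
  })
}

#' Time at which a retention curve falls below a level
#'
#' First bin after the curve's maximum whose proportion drops below
#' `level` (the summary used for reporter-release timing), and the end of
#' the last bin at or above `level` (right-censored persistence).
#'
#' @param curve Tibble from [retention_curve()].
#' @param level Proportion level (default 0.5).
#' @return List: `falls_below_s` (start of the first sub-level bin after
#'   the peak; `NA` if never) and `persists_through_s` (end of the last
#'   bin at or above level).
#' @export
retention_halftime <- function(curve, level = 0.5) {
  ok <- !is.na(curve$proportion)
  cv <- curve[ok, ]
  peak <- which.max(cv$proportion)
  after <- which(seq_len(nrow(cv)) > peak & cv$proportion < level)
  falls <- if (length(after)) cv$bin_start_s[after[1]] else NA_real_
  atl <- which(cv$proportion >= level)
  persists <- if (length(atl)) cv$bin_end_s[max(atl)] else NA_real_
  list(falls_below_s = falls, persists_through_s = persists)
}

#' Score pulse-chase fields for reporter-positive vesicles
#'
#' Segments the dextran channel of each field to find labeled
#' macropinosomes, measures each vesicle's reporter ring enrichment
#' (inner/outer ring ratio, no time referencing — fields are single
#' snapshots), and scores a vesicle positive when the ratio meets the
#' positivity threshold. Fractions are reported per timepoint.
#'
#' @param pc Output of [generate_pulse_chase_fields()], or a compatible
#'   list with `fields` (tibble with `timepoint_min`, `dextran`,
#'   `reporter` list-columns) and `pixel_size`.
#' @param rule A [positivity_rule()] (only `threshold` is used:
#'   snapshots have one frame).
#' @param seg A [seg_params()] for the dextran channel; default
#'   `min_area = 0.5` um^2 to keep small macropinosomes.
#' @param geometry A [ring_geometry()].
#' @return Tibble: `timepoint_min`, `n_vesicles`, `n_positive`,
#'   `fraction_positive` (`NA` where a timepoint has no vesicles), plus a
#'   `per_vesicle` attribute with each vesicle's ring ratio.
#' @export
score_pulse_chase <- function(pc, rule = positivity_rule(),
                              seg = seg_params(min_area = 0.5),
                              geometry = ring_geometry()) {
  per <- purrr::pmap_dfr(pc$fields, function(timepoint_min, field,
                                             dextran, reporter, ...) {
    det <- segment_particles(dextran, pc$pixel_size, seg)
    if (nrow(det) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(det)), function(i) {
      rings <- make_ring_masks(det$mask[[i]], geometry, pc$pixel_size)
      if (!rings$usable) return(NULL)
      ratio <- mean(reporter[rings$inner]) / mean(reporter[rings$outer])
      tibble::tibble(timepoint_min = timepoint_min, field = field,
                     x_um = det$x_um[i], y_um = det$y_um[i],
                     ring_ratio = ratio,
                     positive = ratio >= rule$threshold)
    })
  })
  out <- tibble::tibble(timepoint_min = unique(pc$fields$timepoint_min)) |>
    dplyr::left_join(
      per |> dplyr::group_by(.data$timepoint_min) |>
        dplyr::summarise(n_vesicles = dplyr::n(),
                         n_positive = sum(.data$positive),
                         fraction_positive = mean(.data$positive),
                         .groups = "drop"),
      by = "timepoint_min")
  attr(out, "per_vesicle") <- per
  out
}

#' Count reporter-positive vesicles per cell
#'
#' Detects ring/blob-like reporter objects by contrast against the field
#' background (median intensity), applies size bounds, and counts objects
#' per cell. Without a cell mask the whole field is one cell.
#'
#' @param reporter Reporter-channel matrix.
#' @param pixel_size um per pixel.
#' @param cell_mask Optional integer matrix labeling cells (0 =
#'   background); a vesicle is assigned by its centroid.
#' @param area_bounds Vesicle area bounds in um^2 (default 0.5–20).
#' @param contrast_min Minimum object/background intensity ratio.
#' @return Tibble: `cell_id`, `n_vesicles`.
#' @export
count_vesicles_per_cell <- function(reporter, pixel_size, cell_mask = NULL,
                                    area_bounds = c(0.5, 20),
                                    contrast_min = 1.3) {
  bg <- stats::median(reporter)
  det <- segment_particles(reporter, pixel_size,
                           seg_params(threshold = contrast_min * bg,
                                      min_area = area_bounds[1]))
  det <- det[det$area_um2 <= area_bounds[2] &
               det$mean_intensity >= contrast_min * bg, , drop = FALSE]
  cells <- if (is.null(cell_mask)) 1L else
    sort(unique(cell_mask[cell_mask > 0]))
  counts <- stats::setNames(rep(0L, length(cells)), cells)
  if (nrow(det) > 0) {
    cid <- vapply(seq_len(nrow(det)), function(i) {
      if (is.null(cell_mask)) return(1L)
      r <- round(det$y_um[i] / pixel_size) + 1L
      c <- round(det$x_um[i] / pixel_size) + 1L
      as.integer(cell_mask[r, c])
    }, 1L)
    tab <- table(cid[cid > 0])
    counts[names(tab)] <- as.integer(tab)
  }
  tibble::tibble(cell_id = as.integer(names(counts)),
                 n_vesicles = as.integer(counts))
}
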