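#' Frame-linking parameters
#'
#' Similarity cost between a detection in frame `a` and one in frame `b`
#' (gap frames apart) is
#' `dist / (max_displacement * gap) + area_weight * |log(area_b / area_a)|`;
#' pairs with cost above `cost_threshold` are never linked.
#'
#' @param max_displacement um of allowed centroid motion per frame gap.
#' @param area_weight Trade-off between centroid distance and log-area
#'   change (dimensionless).
#' @param cost_threshold Maximum accepted cost.
#' @param max_frame_gap Largest frame gap bridged by a track.
#' @return A `pf_link_params`.
#' @export
link_params <- function(max_displacement = 2, area_weight = 1,
                        cost_threshold = 1.5, max_frame_gap = 1L) {
  stopifnot(max_displacement >= 0, area_weight >= 0, cost_threshold >= 0,
            max_frame_gap >= 0)
  structure(list(max_displacement = max_displacement,
                 area_weight = area_weight,
                 cost_threshold = cost_threshold,
                 max_frame_gap = as.integer(max_frame_gap)),
            class = "pf_link_params")
}

link_cost_matrix <- function(a, b, params, gap = 1) {
  cost <- outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j) {
    d <- sqrt((a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2)
    d / (params$max_displacement * gap) +
      params$area_weight * abs(log(b$area_um2[j] / a$area_um2[i]))
  }))
  matrix(cost, nrow(a), nrow(b))
}

#' Link detections between two frames
#'
#' Greedy one-to-one matching by ascending similarity cost, gated at
#' `cost_threshold`. The result is independent of the input row order of
#' either frame (ties broken deterministically by index).
#'
#' @param a,b Detection tibbles from [segment_particles()] for two
#'   (gap-tolerated) frames.
#' @param params A [link_params()].
#' @param gap Frame gap between `a` and `b` (scales the displacement
#'   gate).
#' @return List with `matches` (tibble `i`, `j`, `cost`; row indices into
#'   `a` and `b`), `unmatched_a`, `unmatched_b`.
#' @export
link_frames <- function(a, b, params = link_params(), gap = 1) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(matches = tibble::tibble(i = integer(), j = integer(),
                                         cost = numeric()),
                unmatched_a = seq_len(nrow(a)),
                unmatched_b = seq_len(nrow(b))))
  }
  cost <- link_cost_matrix(a, b, params, gap)
  cand <- which(cost <= params$cost_threshold, arr.ind = TRUE)
  ord <- order(cost[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- as.integer(cand[k, 1]); j <- as.integer(cand[k, 2])
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out[[length(out) + 1L]] <- tibble::tibble(i = i, j = j,
                                                cost = cost[i, j])
    }
  }
  matches <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(i = integer(), j = integer(), cost = numeric())
  list(matches = matches,
       unmatched_a = which(!used_a), unmatched_b = which(!used_b))
}

#' Assemble per-frame detections into phagocytic events
#'
#' Links detections across frames (bridging gaps up to `max_frame_gap`),
#' discards tracks shorter than `min_length` frames, and attaches
#' engulfment-time anchors. Events expose an `accepted` flag mirroring a
#' manual review step; see [review_events()].
#'
#' @param detections Tibble of detections with a 0-based `frame` column
#'   (rows from [segment_particles()] over all frames, or compatible).
#' @param params A [link_params()].
#' @param engulfment Either a single engulfment frame applied to every
#'   event, a tibble `(event_id, engulfment_frame)`, or `NULL` (anchor
#'   left `NA`, to be annotated later).
#' @param min_length Minimum event length in detections (default 3).
#' @return Tibble of tracked detections with `event_id`,
#'   `engulfment_frame` and `accepted` columns.
#' @export
build_events <- function(detections, params = link_params(),
                         engulfment = NULL, min_length = 3L) {
  stopifnot(is.data.frame(detections), "frame" %in% names(detections))
  det <- dplyr::arrange(detections, .data$frame)
  det$.track <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 1L
  # active tracks: id -> row index of last detection (in det)
  active <- tibble::tibble(track = integer(), last_row = integer(),
                           last_frame = integer())
  for (f in frames) {
    rows_f <- which(det$frame == f)
    cur <- det[rows_f, ]
    active <- active[f - active$last_frame <= params$max_frame_gap, ]
    if (nrow(active) > 0 && nrow(cur) > 0) {
      prev <- det[active$last_row, ]
      # gap-aware costs: compute per candidate pair with each track's gap
      gaps <- f - active$last_frame
      cost <- matrix(Inf, nrow(prev), nrow(cur))
      for (i in seq_len(nrow(prev))) {
        cost[i, ] <- link_cost_matrix(prev[i, ], cur, params,
                                      gap = gaps[i])
      }
      cand <- which(cost <= params$cost_threshold, arr.ind = TRUE)
      ord <- order(cost[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_t <- logical(nrow(prev)); used_c <- logical(nrow(cur))
      for (k in seq_len(nrow(cand))) {
        i <- as.integer(cand[k, 1]); j <- as.integer(cand[k, 2])
        if (!used_t[i] && !used_c[j]) {
          used_t[i] <- TRUE; used_c[j] <- TRUE
          det$.track[rows_f[j]] <- active$track[i]
          active$last_row[i] <- rows_f[j]
          active$last_frame[i] <- f
        }
      }
      new_rows <- rows_f[!used_c]
    } else {
      new_rows <- rows_f
    }
    for (r in new_rows) {
      det$.track[r] <- next_id
      active <- dplyr::bind_rows(active, tibble::tibble(
        track = next_id, last_row = r, last_frame = f))
      next_id <- next_id + 1L
    }
  }
  keep <- names(which(table(det$.track) >= min_length))
  det <- det[det$.track %in% as.integer(keep), ]
  if (nrow(det) == 0) {
    det$event_id <- integer()
  } else {
    det$event_id <- as.integer(factor(det$.track,
                                      levels = sort(unique(det$.track))))
  }
  det$.track <- NULL
  det$accepted <- TRUE
  det <- annotate_engulfment(det, engulfment)
  tibble::as_tibble(det)
}

#' Attach engulfment-frame anchors to events
#'
#' @param events Event tibble from [build_events()].
#' @param engulfment Single frame index, a tibble
#'   `(event_id, engulfment_frame)`, or `NULL`.
#' @return `events` with an `engulfment_frame` column.
#' @export
annotate_engulfment <- function(events, engulfment) {
  if (is.null(engulfment)) {
    if (!"engulfment_frame" %in% names(events)) {
      events$engulfment_frame <- NA_integer_
    }
    return(events)
  }
  check_frames <- function(fr) {
    if (nrow(events) > 0 &&
        any(fr < min(events$frame) - 60 | fr > max(events$frame))) {
      stop("engulfment annotation references a nonexistent frame")
    }
  }
  if (is.data.frame(engulfment)) {
    stopifnot(all(c("event_id", "engulfment_frame") %in% names(engulfment)))
    check_frames(engulfment$engulfment_frame)
    events$engulfment_frame <- NULL
    events <- dplyr::left_join(events, engulfment, by = "event_id")
  } else {
    check_frames(engulfment)
    events$engulfment_frame <- as.integer(engulfment)
  }
  events
}

#' Accept or reject events after visual review
#'
#' Mirrors the manual error-screening step of the original pipeline:
#' rejected events are flagged (and dropped when `drop = TRUE`).
#'
#' @param events Event tibble.
#' @param reject Integer vector of event ids to reject.
#' @param drop Remove rejected events instead of just flagging them.
#' @return The updated event tibble.
#' @export
review_events <- function(events, reject = integer(), drop = TRUE) {
  events$accepted <- !(events$event_id %in% reject)
  if (drop) events <- events[events$accepted, ]
  events
}
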