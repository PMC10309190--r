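#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort enrichment summary
#'
#' Mean fold-enrichment with an SEM ribbon per condition, with thin lines
#' for the individual experiments behind it.
#'
#' @param agg Output of [aggregate_cohort()].
#' @return A ggplot.
#' @export
plot_trace_cohort <- function(agg) {
  ggplot2::ggplot(agg$summary,
                  ggplot2::aes(x = .data$t_s / 60, y = .data$mean,
                               colour = .data$condition)) +
    ggplot2::geom_line(
      data = agg$by_experiment,
      ggplot2::aes(y = .data$exp_mean,
                   group = interaction(.data$condition, .data$experiment)),
      linewidth = 0.3, alpha = 0.5) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem,
                   fill = .data$condition),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Time after engulfment (min)",
                  y = "Fold enrichment (ref. -10 s)") +
    ggplot2::theme_classic()
}

#' Plot a retention curve
#'
#' Thick line: proportion of events reporter-positive per time bin; thin
#' segments: each event's positive interval.
#'
#' @param curve Tibble from [retention_curve()].
#' @param intervals Optional tibble from [positive_intervals()].
#' @return A ggplot.
#' @export
plot_retention <- function(curve, intervals = NULL) {
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$bin_start_s / 60,
                                    y = .data$proportion)) +
    ggplot2::geom_step(linewidth = 1.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time after engulfment (min)",
                  y = "Proportion positive") +
    ggplot2::theme_classic()
  if (!is.null(intervals) && nrow(intervals) > 0) {
    iv <- dplyr::mutate(intervals,
                        yy = 1 - dplyr::dense_rank(.data$event_id) /
                          (dplyr::n_distinct(.data$event_id) + 1))
    p <- p + ggplot2::geom_segment(
      data = iv,
      ggplot2::aes(x = .data$start_s / 60, xend = .data$end_s / 60,
                   y = .data$yy, yend = .data$yy),
      linewidth = 0.4, alpha = 0.6, colour = "grey40")
  }
  p
}

#' @export
autoplot.pf_binding_fit <- function(object, ...) {
  pts <- object$data |>
    dplyr::group_by(.data$conc_nM) |>
    dplyr::summarise(mean = mean(.data$intensity),
                     sd = stats::sd(.data$intensity), .groups = "drop")
  grid <- tibble::tibble(
    conc_nM = exp(seq(log(max(min(pts$conc_nM), 1e-3)),
                      log(max(pts$conc_nM)), length.out = 200)))
  grid$fit <- one_site(grid$conc_nM, object$kd, object$bmax,
                       object$nonspecific)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc_nM, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.05) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Probe concentration (nM)",
                  y = "Bead fluorescence (a.u.)",
                  subtitle = sprintf("apparent Kd = %.1f +/- %.1f nM",
                                     object$kd, object$kd_error)) +
    ggplot2::theme_classic()
}

#' @export
autoplot.pf_mass_fit <- function(object, binwidth = 5, ...) {
  x <- tibble::tibble(mass = object$masses)
  grid <- tibble::tibble(mass = seq(min(object$masses), max(object$masses),
                                    length.out = 400))
  dens <- rowSums(vapply(seq_len(object$k), function(j) {
    cm <- object$components[j, ]
    cm$fraction * stats::dnorm(grid$mass, cm$mean, cm$sd)
  }, numeric(nrow(grid))))
  grid$count <- dens * object$n_events * binwidth
  ggplot2::ggplot(x, ggplot2::aes(x = .data$mass)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey80",
                            colour = "grey50") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$count),
                       colour = "firebrick") +
    ggplot2::labs(x = "Apparent mass (kD)", y = "Events") +
    ggplot2::theme_classic()
}

#' @export
autoplot.pf_selectivity <- function(object, ...) {
  ggplot2::ggplot(object$per_lipid,
                  ggplot2::aes(x = .data$lipid, y = .data$mean_intensity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Mean intensity (a.u.)",
                  subtitle = sprintf("%s selectivity: %.1f-fold",
                                     object$selective_lipid, object$ratio)) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
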