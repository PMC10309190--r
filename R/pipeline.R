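# Pipeline orchestration: YAML run configs tie the stages into
# reproducible runs with fixed CSV schemas and a machine-readable
# manifest. The functions here are the package's command surface.

#' Read and validate a run configuration
#'
#' @param path YAML file with optional blocks `simulate`, `phagosome`,
#'   `binding`, `mass`, plus top-level `seed` and `out_dir`.
#' @return The config list with `config_path` and `config_hash`
#'   (md5 of the file) attached.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  cfg$config_hash <- unname(tools::md5sum(path))
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

require_field <- function(cfg, block, field) {
  val <- cfg[[block]][[field]]
  if (is.null(val)) {
    stop("config field '", block, ".", field, "' is required")
  }
  val
}

write_pf_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the pipeline (skips the hash header)
#' @param path CSV path.
#' @return A tibble.
#' @export
read_pf_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

write_manifest <- function(out_dir, cfg, counts, files) {
  manifest <- list(
    package = "phagoflux",
    version = as.character(utils::packageVersion("phagoflux")),
    config_hash = cfg$config_hash, seed = cfg$seed,
    counts = counts, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate time-lapse fixtures from a run config
#'
#' The `simulate.scenes` block lists per-event scenes (profile preset,
#' movie length, condition/experiment labels, events per experiment);
#' each event is rendered in its own field and written as TIFF + JSON
#' sidecar, with a `scenes.csv` index.
#'
#' @param cfg Config list from [read_run_config()] (or equivalent).
#' @param out_dir Output directory; default `cfg$out_dir`.
#' @return Tibble index of written scenes, invisibly.
#' @export
run_simulate <- function(cfg, out_dir = cfg$out_dir) {
  scenes <- cfg$simulate$scenes
  if (is.null(scenes)) stop("config field 'simulate.scenes' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  idx <- list(); si <- 0L
  for (sc in scenes) {
    profile <- profile_preset(sc$profile %||% "snxa_phagosome",
                              e_max = sc$e_max %||% 2.5)
    n_events <- sc$n_events %||% 1L
    n_exp <- sc$n_experiments %||% 1L
    for (e in seq_len(n_exp)) for (v in seq_len(n_events)) {
      si <- si + 1L
      seed <- cfg$seed + si
      scene <- single_event_scene(
        profile, movie_min = sc$movie_min %||% 10,
        pre_engulfment_s = sc$pre_engulfment_s %||% 30,
        noise_frac = sc$noise_frac %||% 0.05,
        frame_interval = sc$frame_interval %||% 10,
        pixel_size = sc$pixel_size %||% 0.1,
        image_shape = unlist(sc$image_shape %||% c(96, 96)))
      tl <- generate_timelapse(scene, seed = seed)
      file <- sprintf("%s_exp%d_ev%02d.tif",
                      sc$condition %||% sc$profile %||% "scene", e, v)
      write_timelapse(tl, file.path(out_dir, file))
      idx[[si]] <- tibble::tibble(
        file = file, condition = sc$condition %||% "WT", experiment = e,
        event = v, seed = seed)
    }
  }
  index <- dplyr::bind_rows(idx)
  write_pf_csv(index, file.path(out_dir, "scenes.csv"), cfg$config_hash)
  invisible(index)
}

#' Run the phagosome quantification pipeline
#'
#' For every TIFF in the input directory (guided by `scenes.csv` when
#' present): segment the particle channel per frame, link detections into
#' events, anchor engulfment from the sidecar ground truth, measure ring
#' intensities, compute fold-enrichment traces, extract timings, score
#' positivity, and build per-condition retention curves; then aggregate
#' across experiments. Writes `traces.csv`, `timings.csv`,
#' `retention.csv`, `cohort_summary.csv`, and `manifest.json`. Outputs
#' are deterministic given inputs and config.
#'
#' @param cfg Config from [read_run_config()]; uses the `phagosome`
#'   block (`input_dir` required; optional `seg`, `link`, `rings`,
#'   `positivity`, `reference_time`, `retention_bin_s`).
#' @return List with `traces`, `timings`, `retention`, `cohort`,
#'   invisibly.
#' @export
run_phagosome_pipeline <- function(cfg) {
  input_dir <- require_field(cfg, "phagosome", "input_dir")
  out_dir <- cfg$out_dir %||% input_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- cfg$phagosome
  seg <- do.call(seg_params, ph$seg %||% list())
  lnk <- do.call(link_params, ph$link %||% list())
  geom <- do.call(ring_geometry, ph$rings %||% list())
  rule <- do.call(positivity_rule, ph$positivity %||% list())
  ref_time <- ph$reference_time %||% -10

  idx_path <- file.path(input_dir, "scenes.csv")
  tifs <- list.files(input_dir, pattern = "\\.tiff?$", full.names = FALSE)
  if (length(tifs) == 0) stop("no TIFF stacks found in ", input_dir)
  index <- if (file.exists(idx_path)) read_pf_csv(idx_path) else
    tibble::tibble(file = tifs, condition = "all", experiment = 1L,
                   event = seq_along(tifs))
  counts <- list(stacks = nrow(index), detections = 0L, events_kept = 0L,
                 frames_flagged = 0L)
  traces <- list(); obs_end <- list()
  for (i in seq_len(nrow(index))) {
    tl <- read_timelapse(file.path(input_dir, index$file[i]))
    dets <- purrr::map_dfr(seq_len(tl$n_frames) - 1L, function(f) {
      d <- segment_particles(tl$stack[, , match("particle", tl$channels),
                                      f + 1L], tl$pixel_size, seg)
      if (nrow(d)) d$frame <- f
      d
    })
    counts$detections <- counts$detections + nrow(dets)
    engulf <- tl$ground_truth$particles$engulfment_frame[1]
    events <- build_events(dets, lnk, engulfment = engulf)
    if (nrow(events) == 0) next
    counts$events_kept <- counts$events_kept +
      dplyr::n_distinct(events$event_id)
    meas <- measure_event(tl, events, geom)
    counts$frames_flagged <- counts$frames_flagged +
      attr(meas, "n_flagged")
    tr <- fold_enrichment(meas, reference_time = ref_time)
    tr$condition <- index$condition[i]
    tr$experiment <- index$experiment[i]
    # unique event ids across stacks
    tr$event_id <- paste0(index$condition[i], "_e", index$experiment[i],
                          "_v", index$event[i], "_", tr$event_id)
    traces[[length(traces) + 1L]] <- tr
  }
  if (length(traces) == 0) stop("no usable events in ", input_dir)
  traces <- dplyr::bind_rows(traces)
  timings <- extract_timings(traces, min_peak = rule$threshold)
  intervals <- positive_intervals(traces, rule)
  retention <- traces |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      iv <- positive_intervals(df, rule)
      ends <- tapply(df$t_s, df$event_id, max)
      retention_curve(iv, bin_width = ph$retention_bin_s %||% 60,
                      all_events = names(ends),
                      obs_end = ends)
    }) |>
    dplyr::ungroup()
  cohort <- aggregate_cohort(traces)
  hash <- cfg$config_hash %||% ""
  files <- c("traces.csv", "timings.csv", "retention.csv",
             "cohort_summary.csv")
  write_pf_csv(traces, file.path(out_dir, "traces.csv"), hash)
  write_pf_csv(timings, file.path(out_dir, "timings.csv"), hash)
  write_pf_csv(retention, file.path(out_dir, "retention.csv"), hash)
  write_pf_csv(cohort$summary, file.path(out_dir, "cohort_summary.csv"),
               hash)
  write_manifest(out_dir, cfg, counts, files)
  invisible(list(traces = traces, timings = timings,
                 retention = retention, cohort = cohort,
                 intervals = intervals, counts = counts))
}

#' Run the bead-binding pipeline
#'
#' Reads a mapping CSV (`membrane`, `probe` TIFF paths, `conc_nM`,
#' optional `experiment`), segments bead rings, measures probe intensity
#' per bead, and fits the one-site saturation curve. Writes
#' `beads.csv`, `binding_fit.csv`, and `manifest.json`.
#'
#' @param cfg Config with a `binding` block: `mapping_csv` and
#'   `pixel_size` required.
#' @return The `pf_binding_fit`, invisibly.
#' @export
run_binding_pipeline <- function(cfg) {
  mapping_csv <- require_field(cfg, "binding", "mapping_csv")
  pixel_size <- require_field(cfg, "binding", "pixel_size")
  out_dir <- cfg$out_dir %||% dirname(mapping_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mp <- read_pf_csv(mapping_csv)
  base <- dirname(mapping_csv)
  points <- purrr::map_dfr(seq_len(nrow(mp)), function(i) {
    mem <- tiff::readTIFF(file.path(base, mp$membrane[i]))
    prb <- tiff::readTIFF(file.path(base, mp$probe[i]))
    det <- segment_bead_rings(mem, pixel_size,
                              radius_bounds = unlist(
                                cfg$binding$radius_bounds %||% c(4, 6)))
    if (nrow(det) == 0) return(NULL)
    out <- measure_bead_probe(prb, det, pixel_size)
    out$conc_nM <- mp$conc_nM[i]
    if ("experiment" %in% names(mp)) out$experiment <- mp$experiment[i]
    out$field <- i
    out
  })
  fit <- fit_binding(points, seed = cfg$seed)
  hash <- cfg$config_hash %||% ""
  write_pf_csv(points, file.path(out_dir, "beads.csv"), hash)
  write_pf_csv(glance(fit), file.path(out_dir, "binding_fit.csv"), hash)
  write_manifest(out_dir, cfg, list(fields = nrow(mp),
                                    beads = nrow(points)),
                 c("beads.csv", "binding_fit.csv"))
  invisible(fit)
}

#' Run the mass-photometry pipeline
#'
#' Reads event masses from a one-column CSV (`mass_kd`), or contrasts
#' (`contrast`) plus a standards CSV, calibrates, and fits the Gaussian
#' mixture. Writes `mass_components.csv` and `manifest.json`.
#'
#' @param cfg Config with a `mass` block: `events_csv` required;
#'   optional `standards_csv`, `k`.
#' @return The `pf_mass_fit`, invisibly.
#' @export
run_mass_pipeline <- function(cfg) {
  events_csv <- require_field(cfg, "mass", "events_csv")
  out_dir <- cfg$out_dir %||% dirname(events_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev <- read_pf_csv(events_csv)
  if ("mass_kd" %in% names(ev)) {
    masses <- ev$mass_kd
  } else if ("contrast" %in% names(ev)) {
    std_csv <- require_field(cfg, "mass", "standards_csv")
    cal <- calibrate_mass(read_pf_csv(std_csv))
    masses <- apply_calibration(cal, ev$contrast)
  } else {
    stop("events CSV must contain a 'mass_kd' or 'contrast' column")
  }
  fit <- fit_mass_mixture(masses, k = cfg$mass$k, seed = cfg$seed)
  hash <- cfg$config_hash %||% ""
  write_pf_csv(fit$components, file.path(out_dir, "mass_components.csv"),
               hash)
  write_manifest(out_dir, cfg, list(events = length(masses)),
                 "mass_components.csv")
  invisible(fit)
}
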