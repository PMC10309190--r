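#' Describe one engulfed particle for the time-lapse generator
#'
#' @param x,y Centroid position at frame 0, in micrometres from the
#'   top-left pixel center.
#' @param radius_um Particle radius (um); engulfed yeast are ~1.5 um.
#' @param engulfment_frame 0-based frame index at which engulfment
#'   completes (t = 0 of the recruitment profile).
#' @param profile A [kinetic_profile()] for the first reporter channel.
#' @param profile2 Optional profile for a second reporter channel.
#' @param vx,vy Constant drift (um/s); default stationary.
#' @return A `pf_particle` spec used in [scene_config()].
#' @export
scene_particle <- function(x, y, radius_um, engulfment_frame,
                           profile = profile_preset("snxa_phagosome"),
                           profile2 = NULL, vx = 0, vy = 0) {
  stopifnot(radius_um > 0, engulfment_frame >= 0)
  structure(list(x = x, y = y, radius_um = radius_um,
                 engulfment_frame = as.integer(engulfment_frame),
                 profile = profile, profile2 = profile2, vx = vx, vy = vy),
            class = "pf_particle")
}

#' Scene configuration for the synthetic time-lapse generator
#'
#' Defines the imaging geometry and contents of a synthetic phagocytosis
#' movie. Defaults emulate the acquisition used for the reporter movies:
#' 0.1 um pixels, one frame every 10 s.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval Seconds between frames.
#' @param n_frames Number of frames.
#' @param particles List of [scene_particle()] specs.
#' @param cytosol_mean Mean cytosolic reporter intensity (a.u.).
#' @param noise_sd Additive Gaussian noise sd (a.u.); default 5% of
#'   `cytosol_mean`.
#' @param shot_noise Add Poisson shot noise before the Gaussian term.
#' @param particle_intensity Yeast-channel disk intensity (a.u.).
#' @param phrodo Render pHrodo acidification: the particle channel ramps
#'   up 2-fold starting 60 s post-engulfment (pH proxy only; never used as
#'   a threshold downstream).
#' @param shell_width_um Width of the rendered membrane shell outside the
#'   particle perimeter carrying the reporter enrichment signal. Must
#'   exceed the inner-ring outer edge of the measurement geometry and stay
#'   inside the background-ring gap.
#' @param two_reporters Render a second reporter channel (uses each
#'   particle's `profile2`, falling back to `profile`).
#' @return A `pf_scene_config`.
#' @export
scene_config <- function(image_shape = c(512, 512), pixel_size = 0.1,
                         frame_interval = 10, n_frames = 60,
                         particles = list(), cytosol_mean = 100,
                         noise_sd = 0.05 * cytosol_mean, shot_noise = FALSE,
                         particle_intensity = 150, phrodo = TRUE,
                         shell_width_um = 0.65, two_reporters = FALSE) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  stopifnot(n_frames >= 1, cytosol_mean > 0, shell_width_um > 0)
  for (p in particles) {
    stopifnot(inherits(p, "pf_particle"))
    if (p$engulfment_frame >= n_frames) {
      stop("engulfment_frame must lie within [0, n_frames)")
    }
    if (p$radius_um < 2 * pixel_size) {
      stop("particle radius must be >= 2 * pixel_size")
    }
  }
  structure(list(image_shape = image_shape, pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = n_frames,
                 particles = particles, cytosol_mean = cytosol_mean,
                 noise_sd = noise_sd, shot_noise = shot_noise,
                 particle_intensity = particle_intensity, phrodo = phrodo,
                 shell_width_um = shell_width_um,
                 two_reporters = two_reporters),
            class = "pf_scene_config")
}

particle_position <- function(p, t_abs) {
  c(x = p$x + p$vx * t_abs, y = p$y + p$vy * t_abs)
}

check_scene_valid <- function(config) {
  cfg <- config
  h <- cfg$image_shape[1] * cfg$pixel_size
  w <- cfg$image_shape[2] * cfg$pixel_size
  margin <- cfg$shell_width_um + 0.7  # room for the background ring
  times <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  for (t in range(times)) {
    pos <- lapply(cfg$particles, particle_position, t_abs = t)
    for (i in seq_along(pos)) {
      p <- cfg$particles[[i]]
      r <- p$radius_um + margin
      if (pos[[i]]["x"] < r || pos[[i]]["y"] < r ||
          pos[[i]]["x"] > w - cfg$pixel_size - r ||
          pos[[i]]["y"] > h - cfg$pixel_size - r) {
        stop("particle ", i, " leaves the usable frame area")
      }
      if (i > 1) for (j in seq_len(i - 1)) {
        sep <- sqrt(sum((unlist(pos[[i]]) - unlist(pos[[j]]))^2))
        min_sep <- p$radius_um + cfg$particles[[j]]$radius_um + 2 * margin
        if (sep < min_sep) stop("particles ", j, " and ", i, " overlap")
      }
    }
  }
  invisible(TRUE)
}

render_frame <- function(config, frame) {
  cfg <- config
  shape <- cfg$image_shape
  t_abs <- frame * cfg$frame_interval
  n_rep <- if (cfg$two_reporters) 2L else 1L
  chans <- array(0, dim = c(shape[1], shape[2], 1L + n_rep))
  chans[, , 2:(1 + n_rep)] <- cfg$cytosol_mean
  for (p in cfg$particles) {
    pos <- particle_position(p, t_abs)
    rho <- radial_dist(shape, cfg$pixel_size, pos["x"], pos["y"])
    t_rel <- t_abs - p$engulfment_frame * cfg$frame_interval
    disk <- rho <= p$radius_um
    intensity <- cfg$particle_intensity
    if (cfg$phrodo && t_rel >= 60) {
      intensity <- intensity * (1 + pmin(1, (t_rel - 60) / 300))
    }
    chans[, , 1][disk] <- intensity
    shell <- rho > p$radius_um & rho <= p$radius_um + cfg$shell_width_um
    profs <- list(p$profile, p$profile2 %||% p$profile)
    for (k in seq_len(n_rep)) {
      chans[, , 1 + k][shell] <- cfg$cytosol_mean *
        profile_eval(profs[[k]], t_rel)
    }
  }
  chans
}

#' Generate a synthetic phagocytosis time-lapse with ground truth
#'
#' Renders a multi-channel movie: a particle channel carrying each
#' engulfed yeast as a disk (with optional pHrodo brightening after
#' engulfment) and one or two reporter channels in which a membrane shell
#' at each particle's boundary carries intensity
#' `cytosol_mean * profile_eval(t - t_engulfment)` before noise. The same
#' `(config, seed)` always yields a bit-identical stack.
#'
#' @param config A [scene_config()].
#' @param seed Integer RNG seed.
#' @return A `pf_timelapse`: list with `stack` (array `H x W x C x T`),
#'   `channels`, `pixel_size`, `frame_interval`, and `ground_truth`
#'   (particle table plus per-frame track).
#' @export
generate_timelapse <- function(config, seed = 1L) {
  stopifnot(inherits(config, "pf_scene_config"))
  check_scene_valid(config)
  cfg <- config
  n_rep <- if (cfg$two_reporters) 2L else 1L
  channels <- c("particle", if (n_rep == 1) "reporter" else
                c("reporter1", "reporter2"))
  stack <- array(0, dim = c(cfg$image_shape[1], cfg$image_shape[2],
                            1L + n_rep, cfg$n_frames))
  with_seed(seed, {
    for (f in seq_len(cfg$n_frames) - 1L) {
      fr <- render_frame(cfg, f)
      fr[] <- add_noise(fr, cfg$noise_sd, cfg$shot_noise)
      stack[, , , f + 1L] <- fr
    }
  })
  track <- purrr::imap_dfr(cfg$particles, function(p, i) {
    t_abs <- (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval
    tibble::tibble(
      particle_id = i, frame = seq_len(cfg$n_frames) - 1L,
      x_um = p$x + p$vx * t_abs, y_um = p$y + p$vy * t_abs,
      area_um2 = pi * p$radius_um^2)
  })
  particles <- purrr::imap_dfr(cfg$particles, function(p, i) {
    pr <- p$profile
    tibble::tibble(particle_id = i, radius_um = p$radius_um,
                   engulfment_frame = p$engulfment_frame,
                   t_on = pr$t_on, t_peak = pr$t_peak,
                   t_plateau_end = pr$t_plateau_end, t_off = pr$t_off,
                   e_max = pr$e_max)
  })
  structure(list(stack = stack, channels = channels,
                 pixel_size = cfg$pixel_size,
                 frame_interval = cfg$frame_interval,
                 n_frames = cfg$n_frames,
                 ground_truth = list(particles = particles, track = track),
                 seed = seed),
            class = "pf_timelapse")
}

#' @export
print.pf_timelapse <- function(x, ...) {
  cat(sprintf("<pf_timelapse> %d frames, %d channel(s) [%s], %dx%d px @ %g um/px, dt %g s\n",
              x$n_frames, length(x$channels), paste(x$channels, collapse = ","),
              dim(x$stack)[1], dim(x$stack)[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write a time-lapse to multi-page TIFF with a JSON sidecar
#'
#' Pages are frame-major, channel-interleaved, 16-bit. The sidecar
#' (`<stem>.json`) records pixel size, frame interval, channel names, the
#' intensity scale used for quantization, and the full ground truth, so
#' [read_timelapse()] can reconstruct the object.
#'
#' @param tl A `pf_timelapse`.
#' @param path Output TIFF path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(tl, path) {
  stopifnot(inherits(tl, "pf_timelapse"))
  scale <- max(tl$stack, 1e-12)
  d <- dim(tl$stack)
  pages <- vector("list", d[3] * d[4])
  i <- 1L
  for (f in seq_len(d[4])) for (c in seq_len(d[3])) {
    pages[[i]] <- tl$stack[, , c, f] / scale
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size = tl$pixel_size, frame_interval = tl$frame_interval,
               n_frames = tl$n_frames, channels = tl$channels,
               intensity_scale = scale, seed = tl$seed,
               ground_truth = tl$ground_truth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Read a time-lapse written by [write_timelapse()]
#'
#' Also reads any externally produced multi-page TIFF provided a JSON
#' sidecar names the channels and gives `pixel_size` and `frame_interval`.
#'
#' @param path TIFF path; the sidecar is found by swapping the extension.
#' @return A `pf_timelapse`.
#' @export
read_timelapse <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  n_ch <- length(meta$channels)
  n_fr <- length(pages) / n_ch
  stopifnot(n_fr == round(n_fr))
  scale <- meta$intensity_scale %||% 1
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), n_ch, n_fr))
  i <- 1L
  for (f in seq_len(n_fr)) for (c in seq_len(n_ch)) {
    stack[, , c, f] <- pages[[i]] * scale
    i <- i + 1L
  }
  gt <- meta$ground_truth
  if (!is.null(gt)) {
    gt$particles <- tibble::as_tibble(gt$particles)
    gt$track <- tibble::as_tibble(gt$track)
  }
  structure(list(stack = stack, channels = meta$channels,
                 pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval,
                 n_frames = as.integer(n_fr),
                 ground_truth = gt, seed = meta$seed),
            class = "pf_timelapse")
}

#' Convenience scene: one engulfed particle in a small field
#'
#' Builds a single-particle [scene_config()] sized to hold the particle
#' and both measurement rings, with engulfment after a configurable
#' pre-engulfment window. Used for cohort simulation where each phagocytic
#' event is rendered in its own field.
#'
#' @param profile Recruitment profile for the reporter channel.
#' @param movie_min Movie length (minutes).
#' @param pre_engulfment_s Observation time before engulfment (s); must
#'   cover the -10 s fold-enrichment reference.
#' @param radius_um Particle radius.
#' @param noise_frac Gaussian noise sd as a fraction of the cytosol mean.
#' @param frame_interval,pixel_size Acquisition settings.
#' @inheritParams scene_config
#' @return A `pf_scene_config`.
#' @export
single_event_scene <- function(profile, movie_min = 10, pre_engulfment_s = 30,
                               radius_um = 1.5, noise_frac = 0.05,
                               frame_interval = 10, pixel_size = 0.1,
                               image_shape = c(96, 96), cytosol_mean = 100) {
  n_frames <- as.integer(ceiling(movie_min * 60 / frame_interval)) +
    as.integer(pre_engulfment_s / frame_interval)
  center <- (image_shape - 1) * pixel_size / 2
  part <- scene_particle(x = center[2], y = center[1], radius_um = radius_um,
                         engulfment_frame = pre_engulfment_s / frame_interval,
                         profile = profile)
  scene_config(image_shape = image_shape, pixel_size = pixel_size,
               frame_interval = frame_interval, n_frames = n_frames,
               particles = list(part), cytosol_mean = cytosol_mean,
               noise_sd = noise_frac * cytosol_mean)
}
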