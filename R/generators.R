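#' Synthetic pulse-chase fields of labeled macropinosomes
#'
#' Emulates a dextran pulse-chase experiment: macropinosomes formed during
#' a short labeling pulse carry a dextran-channel disk; the reporter
#' channel carries a membrane shell whose enrichment follows the
#' recruitment profile evaluated at each vesicle's age. At chase timepoint
#' `T` (minutes after dextran addition, pulse of `pulse_min` minutes)
#' vesicle ages are drawn uniformly on `[max(0, T - pulse_min), T]`.
#'
#' @param n_fields Fields of view per timepoint.
#' @param vesicles_per_field Vesicles rendered per field.
#' @param profile Recruitment [kinetic_profile()].
#' @param timepoints_min Sorted chase timepoints (minutes).
#' @param pulse_min Labeling-pulse duration (minutes).
#' @param seed RNG seed.
#' @param pixel_size um/px; `field_shape` in pixels.
#' @param radius_range Vesicle radius range (um), drawn uniformly.
#' @param cytosol_mean Reporter cytosol intensity (a.u.).
#' @param noise_frac Gaussian noise sd as fraction of `cytosol_mean`.
#' @param positive_threshold Fold-enrichment above which a vesicle's
#'   ground-truth label is "positive".
#' @param field_shape Field size in pixels `c(height, width)`.
#' @return List with `fields` (tibble; `dextran`/`reporter` list-columns
#'   of matrices), `ground_truth` (per-vesicle age, enrichment, label) and
#'   the generator parameters.
#' @export
generate_pulse_chase_fields <- function(n_fields = 3, vesicles_per_field = 20,
                                        profile = profile_preset("snxa_macropinosome"),
                                        timepoints_min = c(0, 2, 4, 6, 8, 10),
                                        pulse_min = 2, seed = 1L,
                                        pixel_size = 0.1,
                                        radius_range = c(0.7, 1.0),
                                        cytosol_mean = 100, noise_frac = 0.05,
                                        positive_threshold = 1.5,
                                        field_shape = c(256, 256)) {
  if (length(timepoints_min) == 0) stop("timepoints_min must be non-empty")
  if (is.unsorted(timepoints_min)) stop("timepoints_min must be sorted")
  shell_w <- 0.65
  margin <- max(radius_range) + shell_w + 0.8
  h_um <- (field_shape[1] - 1) * pixel_size
  w_um <- (field_shape[2] - 1) * pixel_size
  nx <- ceiling(sqrt(vesicles_per_field * w_um / h_um))
  ny <- ceiling(vesicles_per_field / nx)
  cw <- (w_um - 2 * margin) / nx
  ch <- (h_um - 2 * margin) / ny
  if (min(cw, ch) < 2 * max(radius_range) + 1.4) {
    stop("field too small for the requested number of non-overlapping vesicles")
  }
  jit <- pmax(0, (min(cw, ch) - 2 * max(radius_range) - 1.4) / 2)

  fields <- list(); gt <- list()
  with_seed(seed, {
    for (tp in timepoints_min) {
      age_lo <- max(0, tp - pulse_min) * 60
      age_hi <- tp * 60
      for (f in seq_len(n_fields)) {
        dex <- matrix(10, field_shape[1], field_shape[2])
        rep_ch <- matrix(cytosol_mean, field_shape[1], field_shape[2])
        slots <- sample(nx * ny, vesicles_per_field)
        for (v in seq_len(vesicles_per_field)) {
          s <- slots[v]
          gx <- (s - 1) %% nx; gy <- (s - 1) %/% nx
          x0 <- margin + (gx + 0.5) * cw + stats::runif(1, -jit, jit)
          y0 <- margin + (gy + 0.5) * ch + stats::runif(1, -jit, jit)
          r <- stats::runif(1, radius_range[1], radius_range[2])
          age <- stats::runif(1, age_lo, age_hi)
          enr <- profile_eval(profile, age)
          rho <- radial_dist(field_shape, pixel_size, x0, y0)
          dex[rho <= r] <- 150
          rep_ch[rho > r & rho <= r + shell_w] <- cytosol_mean * enr
          gt[[length(gt) + 1L]] <- tibble::tibble(
            timepoint_min = tp, field = f, vesicle = v, x_um = x0, y_um = y0,
            radius_um = r, age_s = age, enrichment = enr,
            positive = enr >= positive_threshold)
        }
        sd_abs <- noise_frac * cytosol_mean
        fields[[length(fields) + 1L]] <- tibble::tibble(
          timepoint_min = tp, field = f,
          dextran = list(add_noise(dex, sd_abs)),
          reporter = list(add_noise(rep_ch, sd_abs)))
      }
    }
  })
  list(fields = dplyr::bind_rows(fields), ground_truth = dplyr::bind_rows(gt),
       pixel_size = pixel_size, pulse_min = pulse_min,
       positive_threshold = positive_threshold, seed = seed)
}

#' One-site binding parameter presets for the bead assay
#'
#' Apparent affinities of the PI(3,5)P2 probes measured on membrane-coated
#' beads: 187.3 nM for full-length SnxA (`"snxa_fl"`), 217.5 nM for the
#' tandem-PX construct (`"px2"`). `bmax` is in arbitrary intensity units.
#'
#' @param name Preset name.
#' @return List with `kd` (nM), `bmax`, `nonspecific`.
#' @export
binding_preset <- function(name = c("snxa_fl", "px2")) {
  name <- match.arg(name)
  switch(name,
    snxa_fl = list(kd = 187.3, bmax = 1, nonspecific = 0),
    px2     = list(kd = 217.5, bmax = 1, nonspecific = 0))
}

#' Synthetic equatorial-section image of membrane-coated beads
#'
#' Renders each 10-um-class bead as a bright circle (equatorial ring) in
#' the membrane-dye channel; the probe channel's ring intensity before
#' noise is `nonspecific + bmax * conc / (true_kd + conc)` on top of a
#' constant off-bead background.
#'
#' @param true_kd Ground-truth apparent Kd (nM).
#' @param bmax Saturating specific intensity (a.u.).
#' @param nonspecific Concentration-independent ring intensity (a.u.).
#' @param conc Probe concentration (nM, >= 0).
#' @param n_beads Beads in the field (>= 1).
#' @param bead_radius_um Equatorial radius (um).
#' @param seed RNG seed.
#' @param pixel_size um/px.
#' @param ring_thickness_px Rendered ring thickness (pixels).
#' @param noise_sd Gaussian noise sd on the probe channel (a.u.).
#' @param probe_background Off-bead probe intensity (a.u.).
#' @return List with `membrane` and `probe` matrices plus a per-bead
#'   `ground_truth` tibble.
#' @export
generate_bead_field <- function(true_kd, bmax = 1, nonspecific = 0, conc,
                                n_beads = 30, bead_radius_um = 5, seed = 1L,
                                pixel_size = 0.2, ring_thickness_px = 3,
                                noise_sd = 0.05 * bmax,
                                probe_background = 0.1 * bmax) {
  stopifnot(conc >= 0, n_beads >= 1, true_kd > 0)
  spacing <- 2 * bead_radius_um + 3
  nx <- ceiling(sqrt(n_beads))
  ny <- ceiling(n_beads / nx)
  shape <- c(ceiling(ny * spacing / pixel_size) + 10,
             ceiling(nx * spacing / pixel_size) + 10)
  membrane <- matrix(0.02, shape[1], shape[2])
  probe <- matrix(probe_background, shape[1], shape[2])
  signal <- nonspecific + bmax * conc / (true_kd + conc)
  half_t <- ring_thickness_px * pixel_size / 2
  gt <- list()
  with_seed(seed, {
    for (b in seq_len(n_beads)) {
      gx <- (b - 1) %% nx; gy <- (b - 1) %/% nx
      x0 <- (gx + 0.5) * spacing + stats::runif(1, -0.5, 0.5)
      y0 <- (gy + 0.5) * spacing + stats::runif(1, -0.5, 0.5)
      rho <- radial_dist(shape, pixel_size, x0, y0)
      ring <- abs(rho - bead_radius_um) <= half_t
      membrane[ring] <- 1
      probe[ring] <- probe_background + signal
      gt[[b]] <- tibble::tibble(bead = b, x_um = x0, y_um = y0,
                                radius_um = bead_radius_um,
                                true_intensity = signal)
    }
    gt <- dplyr::bind_rows(gt)
    d <- as.matrix(stats::dist(gt[, c("x_um", "y_um")]))
    diag(d) <- Inf
    if (any(d < 2 * bead_radius_um + ring_thickness_px * pixel_size)) {
      stop("beads overlap beyond tolerance")
    }
    membrane <- add_noise(membrane, 0.01)
    probe <- add_noise(probe, noise_sd)
  })
  list(membrane = membrane, probe = probe, ground_truth = gt,
       pixel_size = pixel_size, conc = conc, true_kd = true_kd,
       bmax = bmax, nonspecific = nonspecific,
       probe_background = probe_background, seed = seed)
}

#' Mass-photometry mixture specifications and presets
#'
#' `mass_mixture_spec()` validates a Gaussian mixture over event masses;
#' `mass_preset()` returns the compositions observed for the recombinant
#' probes: the 1xPX and 2xPX fusions are single populations at 92 and
#' 104 kD, while 85% of full-length SnxA runs at 181 kD (a dimer) with the
#' remainder near the 92-kD monomer weight. Spread defaults (12 kD for
#' the full-length mixture, 10 kD for the monomer controls) are generator
#' choices; the instrument spread is not published.
#'
#' @param means,sds,fractions Component parameters (kD; fractions sum to
#'   1 within 1e-9; sds >= 0).
#' @param n_events Events to draw.
#' @return A `pf_mass_spec`.
#' @export
mass_mixture_spec <- function(means, sds, fractions, n_events) {
  stopifnot(length(means) == length(sds), length(means) == length(fractions),
            all(sds >= 0), n_events >= 1)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(means = means, sds = sds, fractions = fractions,
                 n_events = as.integer(n_events)),
            class = "pf_mass_spec")
}

#' @rdname mass_mixture_spec
#' @param name Preset: `"snxa_fl"`, `"px1"`, `"px2"`.
#' @export
mass_preset <- function(name = c("snxa_fl", "px1", "px2"), n_events = 5000) {
  name <- match.arg(name)
  switch(name,
    snxa_fl = mass_mixture_spec(c(92, 181), c(12, 12), c(0.15, 0.85), n_events),
    px1     = mass_mixture_spec(92, 10, 1, n_events),
    px2     = mass_mixture_spec(104, 10, 1, n_events))
}

#' Draw event masses from a Gaussian mixture
#'
#' @param spec A [mass_mixture_spec()].
#' @param seed RNG seed; the same seed gives an identical event list.
#' @return Numeric vector of event masses (kD).
#' @export
generate_mass_events <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pf_mass_spec"))
  with_seed(seed, {
    comp <- sample(length(spec$means), spec$n_events, replace = TRUE,
                   prob = spec$fractions)
    stats::rnorm(spec$n_events, mean = spec$means[comp], sd = spec$sds[comp])
  })
}

#' Synthetic lipid-array intensity panel
#'
#' Emulates quantification of a protein-lipid overlay array: one lipid is
#' bound with `fold_preference`-fold higher mean intensity than every
#' other spotted lipid. Default lipids are the seven phosphoinositides
#' with PI(3,5)P2 as the selective target.
#'
#' @param selective_lipid Name of the preferred lipid.
#' @param fold_preference Mean-intensity fold preference (>= 1).
#' @param lipids Character vector of lipid names (must include
#'   `selective_lipid` unless `fold_preference` is irrelevant).
#' @param n_replicates Spots per lipid.
#' @param noise_frac Relative Gaussian noise per spot.
#' @param base_intensity Mean intensity of non-selective lipids (a.u.).
#' @param seed RNG seed.
#' @return Tidy tibble `(lipid, replicate, intensity)` with the ground
#'   truth attached as attributes.
#' @export
generate_lipid_panel <- function(selective_lipid = "PI(3,5)P2",
                                 fold_preference = 20,
                                 lipids = c("PI(3)P", "PI(4)P", "PI(5)P",
                                            "PI(3,4)P2", "PI(3,5)P2",
                                            "PI(4,5)P2", "PI(3,4,5)P3"),
                                 n_replicates = 8, noise_frac = 0.05,
                                 base_intensity = 50, seed = 1L) {
  if (fold_preference < 1) stop("fold_preference must be >= 1")
  if (!selective_lipid %in% lipids) stop("selective_lipid must be in lipids")
  means <- stats::setNames(rep(base_intensity, length(lipids)), lipids)
  means[selective_lipid] <- fold_preference * base_intensity
  out <- with_seed(seed, {
    tidyr::expand_grid(lipid = lipids, replicate = seq_len(n_replicates)) |>
      dplyr::mutate(intensity = means[.data$lipid] *
                      (1 + stats::rnorm(dplyr::n(), sd = noise_frac)))
  })
  attr(out, "selective_lipid") <- selective_lipid
  attr(out, "fold_preference") <- fold_preference
  out
}
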