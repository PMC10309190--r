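test_that("all generators are bit-reproducible under a fixed seed", {
  sc <- single_event_scene(profile_preset("snxa_macropinosome"),
                           movie_min = 1)
  expect_identical(generate_timelapse(sc, seed = 11)$stack,
                   generate_timelapse(sc, seed = 11)$stack)
  expect_false(identical(generate_timelapse(sc, seed = 11)$stack,
                         generate_timelapse(sc, seed = 12)$stack))

  pc <- function(s) generate_pulse_chase_fields(
    n_fields = 1, vesicles_per_field = 6, timepoints_min = c(2, 4),
    seed = s, field_shape = c(160, 160))
  expect_identical(pc(3)$fields$reporter, pc(3)$fields$reporter)

  bf <- function(s) generate_bead_field(200, conc = 100, n_beads = 4,
                                        seed = s)
  expect_identical(bf(5)$probe, bf(5)$probe)

  expect_identical(generate_mass_events(mass_preset("snxa_fl", 500), 7),
                   generate_mass_events(mass_preset("snxa_fl", 500), 7))
  expect_identical(generate_lipid_panel(seed = 9),
                   generate_lipid_panel(seed = 9))
})

test_that("noiseless rendering puts cytosol_mean * profile in the membrane annulus", {
  # signal fidelity against the analytically defined annulus, checked at
  # the frame level without the segmentation pipeline
  prof <- profile_preset("snxa_macropinosome")
  sc <- single_event_scene(prof, movie_min = 5, noise_frac = 0,
                           pixel_size = 0.1)
  tl <- generate_timelapse(sc, seed = 1)
  p <- tl$ground_truth$particles
  tr <- tl$ground_truth$track[1, ]
  rho <- sqrt(outer(((seq_len(96) - 1) * 0.1 - tr$y_um)^2,
                    rep(1, 96)) +
                t(outer(((seq_len(96) - 1) * 0.1 - tr$x_um)^2, rep(1, 96))))
  annulus <- rho > p$radius_um + 0.2 & rho <= p$radius_um + 0.55
  for (f in c(0, 10, 20, 30)) {
    t_rel <- (f - p$engulfment_frame) * tl$frame_interval
    got <- mean(tl$stack[, , 2, f + 1][annulus])
    expect_equal(got, 100 * profile_eval(prof, t_rel), tolerance = 0.02)
  }
})

test_that("a flat (null) profile gives uniform reporter and unit ring enrichment", {
  tr <- run_single_event(profile_preset("null"), movie_min = 3, seed = 4,
                         noise_frac = 0.05)
  expect_true(all(abs(tr$fold_enrichment - 1) < 0.1))
  # noiseless: statistically uniform reporter channel
  sc <- single_event_scene(profile_preset("null"), movie_min = 1,
                           noise_frac = 0)
  tl <- generate_timelapse(sc, seed = 2)
  expect_equal(max(tl$stack[, , 2, 1]) - min(tl$stack[, , 2, 1]), 0)
})

test_that("scene validation rejects out-of-frame and overlapping particles", {
  p_edge <- scene_particle(0.5, 0.5, 1.5, 0)
  expect_error(scene_config(image_shape = c(64, 64), particles = list(p_edge),
                            n_frames = 2) |> generate_timelapse(),
               "leaves")
  p1 <- scene_particle(4, 4, 1.5, 0)
  p2 <- scene_particle(5, 4.5, 1.5, 0)
  expect_error(generate_timelapse(
    scene_config(image_shape = c(128, 128), particles = list(p1, p2),
                 n_frames = 2)), "overlap")
  expect_error(scene_config(particles = list(scene_particle(5, 5, 0.1, 0))),
               "radius")
  expect_error(scene_config(particles = list(scene_particle(5, 5, 1.5, 99)),
                            n_frames = 10), "engulfment_frame")
  expect_error(scene_config(pixel_size = 0), "pixel_size")
})

test_that("ground truth is complete and survives TIFF+JSON round trip", {
  sc <- scene_config(image_shape = c(128, 128), n_frames = 3,
                     particles = list(scene_particle(4, 4, 1.5, 1),
                                      scene_particle(9, 9, 1.2, 0)))
  tl <- generate_timelapse(sc, seed = 6)
  expect_equal(nrow(tl$ground_truth$particles), 2)
  expect_equal(nrow(tl$ground_truth$track), 2 * 3)
  path <- file.path(withr::local_tempdir(), "scene.tif")
  write_timelapse(tl, path)
  back <- read_timelapse(path)
  expect_equal(back$ground_truth$particles,
               tl$ground_truth$particles)
  expect_equal(back$ground_truth$track, tl$ground_truth$track)
  expect_equal(back$pixel_size, tl$pixel_size)
  expect_equal(back$channels, tl$channels)
  # stack equal up to 16-bit quantization
  expect_lt(max(abs(back$stack - tl$stack)), max(tl$stack) / 65535 * 1.01)
})

test_that("mass-event draws honour the mixture spec", {
  # degenerate sd: all masses at the component mean
  m <- generate_mass_events(mass_mixture_spec(92, 0, 1, 100), seed = 1)
  expect_true(all(m == 92))
  # component fraction within binomial error (oracle: exact binomial CI)
  spec <- mass_mixture_spec(c(92, 181), c(12, 12), c(0.15, 0.85), 10000)
  m <- generate_mass_events(spec, seed = 3)
  heavy <- mean(m > 136.5)  # midpoint; overlap negligible at 12-kD sd
  ci <- stats::binom.test(round(0.85 * 10000), 10000)$conf.int
  expect_gt(heavy, ci[1] - 0.01)
  expect_lt(heavy, ci[2] + 0.01)
  expect_error(mass_mixture_spec(c(92, 181), c(12, 12), c(0.5, 0.4), 100),
               "sum to 1")
})

test_that("bead fields render the one-site signal on the equatorial ring", {
  # conc = 0: ring carries only nonspecific signal over background
  bf0 <- generate_bead_field(200, bmax = 1, nonspecific = 0.3, conc = 0,
                             n_beads = 2, seed = 1, noise_sd = 0)
  ring <- bf0$membrane > 0.5
  expect_equal(unique(round(bf0$probe[ring] - bf0$probe_background, 9)),
               0.3)
  # conc = kd, nonspecific = 0: half saturation identity
  bfk <- generate_bead_field(200, bmax = 1, nonspecific = 0, conc = 200,
                             n_beads = 2, seed = 1, noise_sd = 0)
  ring <- bfk$membrane > 0.5
  expect_equal(unique(round(bfk$probe[ring] - bfk$probe_background, 9)),
               0.5)
})

test_that("lipid panel encodes the requested fold preference", {
  pan1 <- generate_lipid_panel(fold_preference = 1, noise_frac = 0.02,
                               seed = 2)
  expect_equal(selectivity_ratio(pan1)$ratio, 1, tolerance = 0.05)
  expect_error(generate_lipid_panel(fold_preference = 0.5), "fold")
})
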