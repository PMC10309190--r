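test_that("ring masks match the analytic annulus area within 3%", {
  r <- 1.5; ps <- 0.05
  img <- disk_image(c(200, 200), ps, list(c(5, 5)), r)
  det <- segment_particles(img, ps)
  rings <- make_ring_masks(det$mask[[1]], ring_geometry(), ps)
  inner_area <- sum(rings$inner) * ps^2
  outer_area <- sum(rings$outer) * ps^2
  expect_equal(inner_area, pi * ((r + 0.55)^2 - (r + 0.2)^2),
               tolerance = 0.03)
  expect_equal(outer_area, pi * ((r + 1.2)^2 - (r + 0.85)^2),
               tolerance = 0.03)
})

test_that("ring areas converge to the analytic annulus as pixels shrink", {
  r <- 1.5
  errs <- vapply(c(0.12, 0.06, 0.03), function(ps) {
    img <- disk_image(c(round(10 / ps), round(10 / ps)), ps,
                      list(c(5.013, 5.017)), r)
    det <- segment_particles(img, ps)
    rings <- make_ring_masks(det$mask[[1]], ring_geometry(), ps)
    abs(sum(rings$inner) * ps^2 - pi * ((r + 0.55)^2 - (r + 0.2)^2))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("invalid ring geometry is rejected; valid rings are disjoint", {
  expect_error(ring_geometry(inner_gap = 0.85, outer_gap = 0.85),
               "inner_gap")
  expect_error(ring_geometry(thickness = 0), "thickness")
  expect_error(ring_geometry(inner_gap = 0.6, thickness = 0.35,
                             outer_gap = 0.85), "overlap")
  img <- disk_image(c(96, 96), 0.1, list(c(4.8, 4.8)), 1.5)
  det <- segment_particles(img, 0.1)
  rings <- make_ring_masks(det$mask[[1]], ring_geometry(), 0.1)
  expect_equal(sum(rings$inner & rings$outer), 0)
  pm <- phagoflux:::mask_matrix(det$mask[[1]])
  expect_equal(sum(pm & (rings$inner | rings$outer)), 0)
})

test_that("border-clipped rings are flagged unusable", {
  img <- disk_image(c(64, 64), 0.1, list(c(1.2, 3.2)), 1.0)
  det <- segment_particles(img, 0.1)
  rings <- make_ring_masks(det$mask[[1]], ring_geometry(), 0.1)
  expect_gt(rings$clipped_fraction, 0.1)
  expect_false(rings$usable)
})

test_that("uniform reporter gives inner_mean == outer_mean", {
  sc <- single_event_scene(profile_preset("null"), movie_min = 1,
                           noise_frac = 0)
  tl <- generate_timelapse(sc, seed = 1)
  det <- segment_particles(tl$stack[, , 1, 1], tl$pixel_size)
  det$frame <- 0L
  ev <- build_events(det, engulfment = 0L, min_length = 1L)
  m <- measure_event(tl, ev)
  expect_equal(m$inner_mean, m$outer_mean)
})

test_that("noiseless scene recovers e_max at the plateau within 2% and a flat background", {
  tr <- run_single_event(profile_preset("snxa_macropinosome"),
                         movie_min = 6, seed = 2, noise_frac = 0)
  peak <- dplyr::filter(tr, t_s == 240)
  expect_equal(peak$fold_enrichment, 2.5, tolerance = 0.02)
  # outer ring (background cytosol) stays constant over time
  sc <- single_event_scene(profile_preset("snxa_macropinosome"),
                           movie_min = 6, noise_frac = 0.05)
  tl <- generate_timelapse(sc, seed = 2)
  dets <- purrr::map_dfr(seq_len(tl$n_frames) - 1L, function(f) {
    d <- segment_particles(tl$stack[, , 1, f + 1L], tl$pixel_size)
    d$frame <- f; d
  })
  ev <- build_events(dets, engulfment = 3L)
  m <- measure_event(tl, ev)
  cv <- stats::sd(m$outer_mean) / mean(m$outer_mean)
  # noise-predicted bound: sd/(mean*sqrt(n_outer)), with slack
  expect_lt(cv, 3 * 0.05 / sqrt(min(m$n_outer)))
})

test_that("fold-enrichment is exactly 1 at the reference frame and under constancy", {
  m <- tibble::tibble(event_id = 1L, frame = 0:9, t_s = seq(-30, 60, 10),
                      channel = "reporter", particle_mean = 1,
                      inner_mean = 5, outer_mean = 2.5,
                      n_inner = 10L, n_outer = 10L)
  tr <- fold_enrichment(m)
  expect_equal(tr$fold_enrichment, rep(1, 10))
  expect_equal(tr$fold_enrichment[tr$t_s == -10], 1)
  expect_error(fold_enrichment(dplyr::filter(m, t_s > 0)), "reference")
})

test_that("fold-enrichment is invariant under global intensity gain", {
  sc <- single_event_scene(profile_preset("snxa_macropinosome"),
                           movie_min = 3)
  tl <- generate_timelapse(sc, seed = 5)
  run <- function(tl) {
    dets <- purrr::map_dfr(seq_len(tl$n_frames) - 1L, function(f) {
      d <- segment_particles(tl$stack[, , 1, f + 1L], tl$pixel_size)
      d$frame <- f; d
    })
    ev <- build_events(dets, engulfment = 3L)
    fold_enrichment(measure_event(tl, ev))
  }
  tr1 <- run(tl)
  tl$stack <- tl$stack * 7.31
  tr2 <- run(tl)
  expect_equal(tr1$fold_enrichment, tr2$fold_enrichment, tolerance = 1e-12)
})

test_that("null-profile traces stay within noise of 1", {
  tr <- run_single_event(profile_preset("null"), movie_min = 4, seed = 8)
  expect_lt(max(abs(tr$fold_enrichment - 1)), 0.15)
  expect_false(extract_timing(tr)$positive)
})
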