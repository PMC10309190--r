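test_that("trapezoid traces recover closed-form half-max timings", {
  for (name in c("snxa_phagosome", "snxa_macropinosome",
                 "pikfyve_untreated")) {
    p <- profile_preset(name)
    horizon <- min(p$t_off + 120, 1800)
    tr <- analytic_trace(p, seq(-30, horizon, by = 10))
    tm <- extract_timing(tr)
    cr <- profile_crossings(p)
    expect_equal(tm$t_arrival, cr[["arrival"]], tolerance = 5 / 120)
    expect_equal(tm$t_departure, cr[["departure"]], tolerance = 5 / 200)
    expect_false(tm$censored)
  }
})

test_that("flat traces are never-positive; censored departures are flagged", {
  flat <- tibble::tibble(t_s = seq(-30, 120, 10),
                         fold_enrichment = 1)
  tm <- extract_timing(flat)
  expect_false(tm$positive)
  expect_true(is.na(tm$dwell))
  # apilimod-like: still at plateau when the movie ends
  p <- profile_preset("pikfyve_apilimod")
  tr <- analytic_trace(p, seq(-30, 900, 10))
  tm <- extract_timing(tr)
  expect_true(tm$censored)
  expect_equal(tm$t_departure, 900)
  expect_error(extract_timing(flat[1:3, ]), "5 frames")
})

test_that("timings are invariant to time shifts and enrichment rescaling", {
  p <- profile_preset("snxa_macropinosome")
  t <- seq(-30, 420, by = 10)
  tr <- analytic_trace(p, t)
  base <- extract_timing(tr)
  shifted <- dplyr::mutate(tr, t_s = t_s + 170)
  tm_s <- extract_timing(shifted)
  expect_equal(tm_s$t_arrival - base$t_arrival, 170)
  expect_equal(tm_s$dwell, base$dwell)
  # rescale enrichment above baseline: half-max crossings unchanged
  scaled <- dplyr::mutate(tr, fold_enrichment = 1 + 3 * (fold_enrichment - 1))
  tm_sc <- extract_timing(scaled)
  expect_equal(tm_sc$t_arrival, base$t_arrival, tolerance = 1e-9)
  expect_equal(tm_sc$t_departure, base$t_departure, tolerance = 1e-9)
})

test_that("dwell recovery error stays below one frame across seeded cohorts", {
  p <- profile_preset("pikfyve_untreated")
  cr <- profile_crossings(p)
  true_dwell <- cr[["departure"]] - cr[["arrival"]]
  errs <- withr::with_seed(7, {
    vapply(1:50, function(i) {
      tr <- analytic_trace(p, seq(-30, 420, 10), noise_sd = 0.05)
      abs(extract_timing(tr)$dwell - true_dwell)
    }, 0)
  })
  expect_lte(mean(errs), 10)
})

test_that("positive intervals respect the persistence requirement", {
  tr <- tibble::tibble(event_id = 1L, t_s = seq(0, 90, 10),
                       fold_enrichment = c(1, 2, 1, 2, 2, 2, 1, 1, 2, 1))
  iv <- positive_intervals(tr, positivity_rule(1.5, 2L))
  expect_equal(nrow(iv), 1)       # the lone spikes at 10 and 80 s drop
  expect_equal(iv$start_s, 30)
  expect_equal(iv$end_s, 50)
  expect_false(iv$censored)
})

test_that("retention curves honour positive windows and right-censoring", {
  iv <- tibble::tibble(event_id = 1:5, start_s = 60, end_s = 240,
                       censored = FALSE, obs_end_s = 600)
  rc <- retention_curve(iv, bin_width = 60)
  expect_equal(rc$proportion[rc$bin_start_s %in% c(60, 120, 180)],
               rep(1, 3))
  expect_equal(rc$proportion[rc$bin_start_s %in% c(300, 360)], rep(0, 2))
  # an event filmed only to 120 s leaves later denominators
  iv2 <- tibble::tibble(event_id = 1:2, start_s = c(60, 60),
                        end_s = c(240, 120), censored = c(FALSE, TRUE),
                        obs_end_s = c(600, 120))
  rc2 <- retention_curve(iv2, bin_width = 60)
  expect_equal(rc2$n_observed[rc2$bin_start_s == 300], 1)
  ht <- retention_halftime(rc)
  expect_equal(ht$falls_below_s, 240)
})

test_that("retention proportion never rises after the cohort's last arrival", {
  p <- profile_preset("pikfyve_untreated")
  traces <- withr::with_seed(3, purrr::map_dfr(1:8, function(v) {
    tr <- analytic_trace(p, seq(-30, 600, 10), noise_sd = 0.05)
    tr$event_id <- v
    tr
  }))
  iv <- positive_intervals(traces)
  rc <- retention_curve(iv, bin_width = 60,
                        all_events = unique(traces$event_id),
                        obs_end = 600)
  after <- rc$proportion[rc$bin_start_s >= max(iv$start_s)]
  expect_true(all(diff(after) <= 0))
})

test_that("vesicle counting finds rendered rings and nothing in blank fields", {
  blank <- matrix(100, 128, 128)
  expect_equal(count_vesicles_per_cell(blank, 0.1)$n_vesicles, 0L)
  pc <- generate_pulse_chase_fields(n_fields = 1, vesicles_per_field = 7,
                                    timepoints_min = 4, seed = 2,
                                    field_shape = c(256, 256))
  rep_ch <- pc$fields$reporter[[1]]
  got <- count_vesicles_per_cell(rep_ch, pc$pixel_size)
  expect_equal(got$n_vesicles, 7L)
})

test_that("vesicle counts decay to zero as reporter contrast is lost", {
  # apilimod washout: ring contrast decays with a 3-min half-time;
  # by 10 min the probe is effectively cytosolic and no vesicle remains
  counts <- vapply(c(0, 3, 6, 10), function(t_min) {
    e_now <- 1 + 1.5 * 2^(-t_min / 3)
    pc <- generate_pulse_chase_fields(
      n_fields = 1, vesicles_per_field = 6,
      profile = kinetic_profile(0, 0, Inf, Inf, e_max = max(e_now, 1)),
      timepoints_min = 1, seed = 5, field_shape = c(224, 224))
    sum(count_vesicles_per_cell(pc$fields$reporter[[1]],
                                pc$pixel_size)$n_vesicles)
  }, 0)
  expect_equal(counts[1], 6)
  expect_equal(counts[4], 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("pulse-chase scoring peaks at 4 min and declines past the profile support", {
  pc <- generate_pulse_chase_fields(n_fields = 2, vesicles_per_field = 24,
                                    seed = 21, field_shape = c(320, 320))
  sc <- score_pulse_chase(pc)
  expect_equal(sc$timepoint_min[which.max(sc$fraction_positive)], 4)
  f4 <- sc$fraction_positive[sc$timepoint_min == 4]
  expect_lt(sc$fraction_positive[sc$timepoint_min == 8], f4)
  expect_lt(sc$fraction_positive[sc$timepoint_min == 10], f4)
  # null profile: at most the rule's false-positive allowance
  pcn <- generate_pulse_chase_fields(n_fields = 1, vesicles_per_field = 20,
                                     profile = profile_preset("null"),
                                     timepoints_min = c(2, 6), seed = 22)
  scn <- score_pulse_chase(pcn)
  expect_true(all(scn$fraction_positive <= 0.02))
})
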