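test_that("bead detection finds rendered circles and measures their radii", {
  bf <- generate_bead_field(200, conc = 100, n_beads = 5, seed = 3,
                            noise_sd = 0)
  det <- segment_bead_rings(bf$membrane, bf$pixel_size)
  expect_equal(nrow(det), 5)
  expect_true(all(abs(det$radius_um - 5) / 5 < 0.05))
  expect_warning(
    empty <- segment_bead_rings(matrix(0.02, 64, 64), 0.2), "no bead")
  expect_equal(nrow(empty), 0)
})

test_that("overlapping beads are rejected rather than mismeasured", {
  # render two rings whose circles intersect: they merge into one
  # non-circular component and fail the circularity gate
  ps <- 0.2
  shape <- c(128, 128)
  rho1 <- sqrt(outer(((seq_len(128) - 1) * ps - 12)^2, rep(1, 128)) +
                 t(outer(((seq_len(128) - 1) * ps - 10)^2, rep(1, 128))))
  rho2 <- sqrt(outer(((seq_len(128) - 1) * ps - 12)^2, rep(1, 128)) +
                 t(outer(((seq_len(128) - 1) * ps - 17)^2, rep(1, 128))))
  img <- matrix(0.02, shape[1], shape[2])
  img[abs(rho1 - 5) <= 0.3 | abs(rho2 - 5) <= 0.3] <- 1
  expect_warning(det <- segment_bead_rings(img, ps))
  expect_equal(nrow(det), 0)
  expect_equal(attr(det, "n_rejected"), 1L)
})

test_that("probe measurement subtracts background and hits half-saturation at Kd", {
  bf <- generate_bead_field(200, bmax = 1, nonspecific = 0, conc = 200,
                            n_beads = 6, seed = 4, noise_sd = 0)
  det <- segment_bead_rings(bf$membrane, bf$pixel_size)
  m <- measure_bead_probe(bf$probe, det, bf$pixel_size)
  expect_equal(mean(m$intensity), 0.5, tolerance = 0.05)
  # uniform probe channel -> zero after background subtraction
  uni <- matrix(0.3, nrow(bf$probe), ncol(bf$probe))
  m0 <- measure_bead_probe(uni, det, bf$pixel_size)
  expect_equal(m0$intensity, rep(0, nrow(det)))
})

test_that("noisy per-bead means stay within the CLT bound of ground truth", {
  bf <- generate_bead_field(200, bmax = 1, nonspecific = 0, conc = 400,
                            n_beads = 30, seed = 5, noise_sd = 0.05)
  det <- segment_bead_rings(bf$membrane, bf$pixel_size)
  m <- measure_bead_probe(bf$probe, det, bf$pixel_size)
  bf0 <- generate_bead_field(200, bmax = 1, nonspecific = 0, conc = 400,
                             n_beads = 30, seed = 5, noise_sd = 0)
  m0 <- measure_bead_probe(bf0$probe,
                           segment_bead_rings(bf0$membrane, bf0$pixel_size),
                           bf0$pixel_size)
  bound <- 2 * max(stats::sd(m$intensity), 0.01) / sqrt(30)
  expect_lt(abs(mean(m$intensity) - mean(m0$intensity)), bound)
})

test_that("noiseless one-site fits recover parameters to machine precision", {
  concs <- c(10, 30, 100, 300, 1000, 2000)
  for (kd in c(10, 200, 2000)) for (bmax in c(0.1, 1, 10)) {
    pts <- tibble::tibble(
      conc_nM = rep(concs, each = 3),
      intensity = 0.05 + bmax * rep(concs, each = 3) /
        (kd + rep(concs, each = 3)))
    fit <- fit_binding(pts, n_boot = 0)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
    expect_equal(fit$bmax, bmax, tolerance = 1e-6)
    expect_equal(fit$nonspecific, 0.05, tolerance = 1e-6)
    expect_equal(fit$kd_error, 0)
  }
})

test_that("Kd is gain-invariant while Bmax scales with gain", {
  concs <- rep(c(10, 50, 200, 800, 2000), each = 4)
  pts <- withr::with_seed(6, tibble::tibble(
    conc_nM = concs,
    intensity = 1 * concs / (200 + concs) + rnorm(length(concs), sd = 0.03)))
  f1 <- fit_binding(pts, n_boot = 50, seed = 2)
  f2 <- fit_binding(dplyr::mutate(pts, intensity = intensity * 2),
                    n_boot = 50, seed = 2)
  expect_equal(f2$kd, f1$kd, tolerance = 1e-8)
  expect_equal(f2$bmax, 2 * f1$bmax, tolerance = 1e-8)
})

test_that("degenerate titrations error and sparse ones warn", {
  pts <- tibble::tibble(conc_nM = rep(100, 8), intensity = rnorm(8, 0.5, 0.01))
  expect_error(fit_binding(pts), "concentrations")
  pts3 <- tibble::tibble(conc_nM = rep(c(10, 100, 1000), each = 3),
                         intensity = rep(c(0.1, 0.4, 0.8), each = 3))
  expect_warning(fit_binding(pts3, n_boot = 0), "fewer than 4")
})

test_that("full image pipeline recovers the full-length probe affinity", {
  concs <- round(exp(seq(log(10), log(2000), length.out = 8)))
  pts <- purrr::map_dfr(1:3, function(e) {
    purrr::map_dfr(concs, function(cc) {
      bf <- generate_bead_field(187.3, 1, 0, conc = cc, n_beads = 8,
                                seed = e * 100 + which(concs == cc),
                                noise_sd = 0.05)
      det <- segment_bead_rings(bf$membrane, bf$pixel_size)
      m <- measure_bead_probe(bf$probe, det, bf$pixel_size)
      m$conc_nM <- cc
      m$experiment <- e
      m
    })
  })
  fit <- fit_binding(pts)
  expect_equal(nrow(fit$per_experiment), 3)
  expect_lt(abs(fit$kd - 187.3), pmax(2 * fit$kd_error, 0.1 * 187.3))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "kd"], fit$kd)
  expect_false(glance(fit)$no_binding)
})

test_that("no-binding controls fit as nonspecific-only", {
  # PI(5)P-style control: intensity independent of concentration
  concs <- rep(c(10, 50, 200, 800, 2000), each = 6)
  pts <- withr::with_seed(8, tibble::tibble(
    conc_nM = concs, intensity = 0.05 + rnorm(length(concs), sd = 0.02)))
  fit <- suppressWarnings(fit_binding(pts, n_boot = 0))
  expect_true(fit$no_binding)
})

test_that("Kd uncertainty intervals are calibrated over seeded titrations", {
  concs <- rep(c(10, 50, 200, 800, 2000), each = 6)
  hits <- withr::with_seed(31, vapply(1:200, function(i) {
    pts <- purrr::map_dfr(1:3, function(e) tibble::tibble(
      experiment = e, conc_nM = concs,
      intensity = concs / (200 + concs) + rnorm(length(concs), sd = 0.05)))
    f <- fit_binding(pts)
    abs(f$kd - 200) <= 2 * f$kd_error
  }, TRUE))
  expect_gte(mean(hits), 0.9)
})

test_that("selectivity ratios behave across equal, selective and zero panels", {
  eq <- tidyr::expand_grid(lipid = letters[1:4], replicate = 1:3) |>
    dplyr::mutate(intensity = 10)
  expect_equal(selectivity_ratio(eq, selective_lipid = "a")$ratio, 1)
  pan <- generate_lipid_panel(fold_preference = 20, noise_frac = 0.05,
                              seed = 13)
  expect_gte(selectivity_ratio(pan)$ratio, 18)
  zero <- dplyr::mutate(eq, intensity = ifelse(lipid == "a", 0, 10))
  expect_equal(selectivity_ratio(zero, selective_lipid = "a")$ratio, 0)
  one <- dplyr::filter(eq, lipid == "a")
  expect_error(selectivity_ratio(one, selective_lipid = "a"), "2 lipids")
  neg <- dplyr::mutate(eq, intensity = ifelse(lipid == "b", -5, 10))
  expect_message(selectivity_ratio(neg, selective_lipid = "a"), "clipped")
})
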