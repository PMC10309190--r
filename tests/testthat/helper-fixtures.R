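# Shared fixtures and independent oracles, all built in code.

# Render a disk image by pixel-center membership (same convention as the
# generators, but written independently of them).
disk_image <- function(shape, pixel_size, centers, radii,
                       value = 100, background = 0) {
  img <- matrix(background, shape[1], shape[2])
  y <- (seq_len(shape[1]) - 1) * pixel_size
  x <- (seq_len(shape[2]) - 1) * pixel_size
  for (i in seq_along(radii)) {
    rho <- sqrt(outer(y - centers[[i]][2], rep(1, shape[2]))^2 +
                  outer(rep(1, shape[1]), x - centers[[i]][1])^2)
    img[rho <= radii[i]] <- value
  }
  img
}

# Super-sampled area oracle: fraction of a region covered by the set
# rho in (r_lo, r_hi], integrated on a grid refined `factor`-fold.
supersampled_annulus_area <- function(r_lo, r_hi, factor = 10) {
  step <- r_hi / (factor * 100)
  g <- seq(-r_hi - step, r_hi + step, by = step)
  rho <- sqrt(outer(g, g, function(a, b) a^2 + b^2))
  sum(rho > r_lo & rho <= r_hi) * step^2
}

# Brute-force minimum-total-cost assignment over all permutations
# (n <= 6). Returns matched pairs (i, j) minimizing summed cost, with
# unmatchable pairs (cost above gate) forbidden.
brute_force_assignment <- function(cost, gate) {
  n_a <- nrow(cost); n_b <- ncol(cost)
  stopifnot(n_a <= 6, n_b <= 6)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  idx_b <- seq_len(n_b)
  # enumerate injective partial mappings a -> b via permutations of b
  # (pad b with "unmatched" slots)
  slots <- c(idx_b, rep(NA_integer_, n_a))
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i], k - 1)
      for (r in rest) out[[length(out) + 1L]] <- c(v[i], r)
    }
    out
  }
  for (p in perms(slots, n_a)) {
    tot <- 0; n_m <- 0L; ok <- TRUE
    for (i in seq_len(n_a)) {
      j <- p[i]
      if (!is.na(j)) {
        if (cost[i, j] > gate) { ok <- FALSE; break }
        tot <- tot + cost[i, j]; n_m <- n_m + 1L
      }
    }
    if (!ok) next
    # maximize matches first, then minimize cost (a matching that links
    # everything it can, as the tracker does)
    if (n_m > best_n || (n_m == best_n && tot < best_cost)) {
      best <- p; best_n <- n_m; best_cost <- tot
    }
  }
  pairs <- tibble::tibble(i = seq_len(n_a), j = best)
  pairs[!is.na(pairs$j), ]
}

# Analytic enrichment trace (no imaging): profile + iid Gaussian noise.
analytic_trace <- function(profile, t, noise_sd = 0, event_id = 1L) {
  tibble::tibble(event_id = event_id, t_s = t,
                 fold_enrichment = profile_eval(profile, t) +
                   stats::rnorm(length(t), sd = noise_sd))
}

# Detection tibble without images, for linker tests.
fake_detections <- function(x, y, area) {
  tibble::tibble(x_um = x, y_um = y, area_um2 = area,
                 label = seq_along(x), mean_intensity = 1,
                 mask = replicate(length(x), NULL, simplify = FALSE))
}

# End-to-end single-event run: image stack -> trace.
run_single_event <- function(profile, movie_min, seed, noise_frac = 0.05,
                             frame_interval = 10) {
  sc <- single_event_scene(profile, movie_min = movie_min,
                           noise_frac = noise_frac,
                           frame_interval = frame_interval)
  tl <- generate_timelapse(sc, seed = seed)
  dets <- purrr::map_dfr(seq_len(tl$n_frames) - 1L, function(f) {
    d <- segment_particles(tl$stack[, , 1, f + 1L], tl$pixel_size)
    if (nrow(d)) d$frame <- f
    d
  })
  ev <- build_events(dets,
                     engulfment = tl$ground_truth$particles$engulfment_frame[1])
  fold_enrichment(measure_event(tl, ev))
}
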