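#' Calibrate mass-photometry contrasts to molecular mass
#'
#' Ordinary least-squares line through standards of known molecular
#' weight; `apply_calibration()` maps contrasts to kD.
#'
#' @param standards Tibble/data frame with `contrast` and `mass_kd`
#'   (>= 2 standards with distinct contrasts).
#' @return A `pf_mass_calibration` with `slope`, `intercept`, and the
#'   underlying `lm` fit.
#' @export
calibrate_mass <- function(standards) {
  stopifnot(all(c("contrast", "mass_kd") %in% names(standards)))
  if (nrow(standards) < 2) stop("need at least 2 calibration standards")
  if (length(unique(standards$contrast)) < 2) {
    stop("calibration standards have identical contrasts")
  }
  fit <- stats::lm(mass_kd ~ contrast, data = standards)
  structure(list(slope = unname(stats::coef(fit)["contrast"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 fit = fit, standards = tibble::as_tibble(standards)),
            class = "pf_mass_calibration")
}

#' @rdname calibrate_mass
#' @param cal A `pf_mass_calibration`.
#' @param contrast Numeric contrasts to convert.
#' @return `apply_calibration()`: masses in kD.
#' @export
apply_calibration <- function(cal, contrast) {
  stopifnot(inherits(cal, "pf_mass_calibration"))
  cal$intercept + cal$slope * contrast
}

#' @export
print.pf_mass_calibration <- function(x, ...) {
  cat(sprintf("<pf_mass_calibration> mass = %.4g + %.4g * contrast (n = %d standards)\n",
              x$intercept, x$slope, nrow(x$standards)))
  invisible(x)
}

# one EM run from a given initialization; returns params + loglik
em_gaussian <- function(x, means, sds, fractions, max_iter = 300,
                        tol = 1e-6) {
  n <- length(x); k <- length(means)
  sd_floor <- max(stats::sd(x), 1e-8) * 1e-4
  sds <- pmax(sds, sd_floor)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(fractions[j]) + stats::dnorm(x, means[j], sds[j], log = TRUE)
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    r <- exp(logd - lse)
    nk <- colSums(r)
    fractions <- nk / n
    means <- colSums(r * x) / nk
    sds <- sqrt(pmax(colSums(r * (x - rep(means, each = n))^2) / nk,
                     sd_floor^2))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(means = means, sds = sds, fractions = fractions, loglik = ll,
       degenerate = any(nk < 1) || any(sds <= sd_floor * 1.0001))
}

fit_gmm_k <- function(x, k, seed, n_restarts) {
  n <- length(x)
  if (length(unique(x)) < k) {
    # fewer distinct masses than components: report the collapse rather
    # than fitting
    u <- unique(x)
    mu <- rep_len(u, k)
    return(list(means = mu, sds = rep(max(stats::sd(x), 1e-8) * 1e-4, k),
                fractions = rep(1 / k, k), loglik = -Inf,
                degenerate = TRUE))
  }
  if (k == 1) {
    sdx <- max(stats::sd(x), 1e-12)
    ll <- sum(stats::dnorm(x, mean(x), sdx, log = TRUE))
    return(list(means = mean(x), sds = sdx, fractions = 1,
                loglik = ll, degenerate = FALSE))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seed + r - 1L, {
      km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
      sds <- vapply(seq_len(k), function(j) {
        xs <- x[km$cluster == j]
        if (length(xs) > 1) stats::sd(xs) else stats::sd(x) / k
      }, 0)
      list(means = as.numeric(km$centers), sds = sds,
           fractions = km$size / n)
    })
    fit <- em_gaussian(x, init$means, init$sds, init$fractions)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' Decompose an event-mass distribution into Gaussian populations
#'
#' Expectation-maximization fit of a `k`-component Gaussian mixture to
#' mass-photometry event masses, with seeded k-means initialization and
#' multiple restarts (best likelihood kept). Components are returned
#' sorted by mean. BIC/AIC are reported over `k_range` so the number of
#' populations can be chosen automatically (`k = NULL`). Components with
#' mean below ~100 kD carry a `low_mass_flag`: apparent weights of native
#' proteins are unreliable below that range on this technique.
#'
#' @param masses Numeric vector of event masses (kD).
#' @param k Number of components (1–4), or `NULL` to select by BIC.
#' @param seed RNG seed for initialization restarts.
#' @param k_range Candidate component counts scored for model selection.
#' @param n_restarts EM restarts per `k`.
#' @return A `pf_mass_fit`: `components` tibble (`mean`, `sd`,
#'   `fraction`, `low_mass_flag`), `k`, `loglik`, `bic`,
#'   `model_selection` tibble, `n_events`, `degenerate`.
#' @export
fit_mass_mixture <- function(masses, k = NULL, seed = 1L, k_range = 1:4,
                             n_restarts = 10L) {
  masses <- masses[is.finite(masses)]
  n <- length(masses)
  if (n < 200) warning("fewer than 200 events; population fractions will ",
                       "be unstable")
  stopifnot(is.null(k) || (k >= 1 && k <= 4))
  ks <- sort(unique(c(k_range, k)))
  fits <- lapply(ks, function(kk) fit_gmm_k(masses, kk, seed, n_restarts))
  sel <- tibble::tibble(
    k = ks,
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_params = 3L * ks - 1L,
    bic = -2 * vapply(fits, `[[`, 0, "loglik") + (3 * ks - 1) * log(n),
    aic = -2 * vapply(fits, `[[`, 0, "loglik") + 2 * (3 * ks - 1))
  if (is.null(k)) k <- sel$k[which.min(sel$bic)]
  fit <- fits[[match(k, ks)]]
  ord <- order(fit$means)
  comps <- tibble::tibble(component = seq_len(k),
                          mean = fit$means[ord], sd = fit$sds[ord],
                          fraction = fit$fractions[ord],
                          low_mass_flag = fit$means[ord] < 100)
  if (isTRUE(fit$degenerate)) {
    warning("degenerate component collapse detected; k likely exceeds ",
            "the distinct support of the data")
  }
  structure(list(components = comps, k = k, loglik = fit$loglik,
                 bic = sel$bic[match(k, sel$k)], model_selection = sel,
                 n_events = n, degenerate = isTRUE(fit$degenerate),
                 masses = masses, seed = seed),
            class = "pf_mass_fit")
}

#' @export
print.pf_mass_fit <- function(x, ...) {
  cat(sprintf("<pf_mass_fit> %d component(s), n = %d events, BIC = %.1f\n",
              x$k, x$n_events, x$bic))
  for (i in seq_len(nrow(x$components))) {
    with(x$components[i, ], cat(sprintf(
      "  %.1f kD (sd %.1f), fraction %.3f%s\n", mean, sd, fraction,
      if (low_mass_flag) " [mean < 100 kD: apparent mass unreliable]" else "")))
  }
  invisible(x)
}

#' @export
tidy.pf_mass_fit <- function(x, ...) x$components

#' @export
glance.pf_mass_fit <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik, bic = x$bic,
                 n_events = x$n_events, degenerate = x$degenerate)
}
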