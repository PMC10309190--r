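#' Piecewise-linear recruitment profile
#'
#' A `kinetic_profile` describes reporter fold-enrichment on a maturing
#' phagosome or macropinosome as a trapezoid over time after engulfment:
#' baseline (1 by definition) until `t_on`, linear rise to `e_max` at
#' `t_peak`, plateau until `t_plateau_end`, linear fall back to baseline at
#' `t_off`. Times are seconds after engulfment. `t_plateau_end` / `t_off`
#' may be `Inf` for reporters retained beyond the observation window.
#'
#' @param t_on Onset of enrichment (s after engulfment).
#' @param t_peak Time of maximal enrichment (s).
#' @param t_plateau_end Time at which decline begins (s); may be `Inf`.
#' @param t_off Time of return to baseline (s); may be `Inf`.
#' @param e_max Peak fold-enrichment (dimensionless, >= 1). `e_max = 1`
#'   encodes a null reporter that never enriches.
#' @return An object of class `kinetic_profile`.
#' @examples
#' p <- kinetic_profile(120, 240, 240, 330, e_max = 2.5)
#' profile_eval(p, c(0, 240, 600))
#' @export
kinetic_profile <- function(t_on, t_peak, t_plateau_end, t_off, e_max = 2.5) {
  stopifnot(is.numeric(t_on), is.numeric(e_max), length(e_max) == 1L)
  if (!(t_on <= t_peak && t_peak <= t_plateau_end && t_plateau_end <= t_off)) {
    stop("profile times must satisfy t_on <= t_peak <= t_plateau_end <= t_off")
  }
  if (e_max < 1) stop("e_max must be >= 1 (baseline is 1 by definition)")
  structure(
    list(t_on = t_on, t_peak = t_peak, t_plateau_end = t_plateau_end,
         t_off = t_off, e_max = e_max, baseline = 1),
    class = "kinetic_profile"
  )
}

#' @export
print.kinetic_profile <- function(x, ...) {
  cat(sprintf(
    "<kinetic_profile> on %gs rise-to %gs plateau-to %gs off %gs, e_max %.3g\n",
    x$t_on, x$t_peak, x$t_plateau_end, x$t_off, x$e_max))
  invisible(x)
}

#' Evaluate a recruitment profile
#'
#' Total function: returns the baseline (1) for any time outside
#' `[t_on, t_off]` and `e_max` on the plateau `[t_peak, t_plateau_end]`,
#' with linear interpolation on the rising and falling edges.
#'
#' @param profile A [kinetic_profile()].
#' @param t Numeric vector of times after engulfment (s); negative values
#'   (pre-engulfment) are allowed and return baseline.
#' @return Numeric vector of fold-enrichment values, same length as `t`.
#' @export
profile_eval <- function(profile, t) {
  stopifnot(inherits(profile, "kinetic_profile"))
  p <- profile
  out <- rep(p$baseline, length(t))
  rise <- t >= p$t_on & t < p$t_peak
  if (p$t_peak > p$t_on) {
    out[rise] <- p$baseline +
      (p$e_max - p$baseline) * (t[rise] - p$t_on) / (p$t_peak - p$t_on)
  }
  out[t >= p$t_peak & t <= p$t_plateau_end] <- p$e_max
  fall <- t > p$t_plateau_end & t < p$t_off
  if (any(fall) && is.finite(p$t_off)) {
    out[fall] <- p$e_max -
      (p$e_max - p$baseline) * (t[fall] - p$t_plateau_end) /
        (p$t_off - p$t_plateau_end)
  }
  out
}

#' Named recruitment-profile presets
#'
#' Presets encode the recruitment timings observed for the PI(3,5)P2
#' reporter SnxA-GFP and for PIKfyve-GFP in *Dictyostelium*:
#'
#' * `"snxa_phagosome"` — arrival (half-max) at 2 min after engulfment,
#'   retained on the phagosome for a further ~20 min.
#' * `"snxa_macropinosome"` — transient: rises from 2 min, peaks at 4 min,
#'   removed by 5–6 min.
#' * `"pikfyve_untreated"` — arrives within 60 s, released by ~4 min.
#' * `"pikfyve_apilimod"` — arrives within 60 s and is never released
#'   within the movie (kinase inhibition blocks dissociation; departure
#'   censored).
#' * `"null"` — e_max = 1; a reporter that never enriches (knockout
#'   control).
#'
#' Peak magnitudes are generator choices (`e_max = 2.5` by default); the
#' timings are the biology.
#'
#' @param name Preset name (see Details).
#' @param e_max Peak fold-enrichment override.
#' @return A [kinetic_profile()].
#' @export
profile_preset <- function(name = c("snxa_phagosome", "snxa_macropinosome",
                                    "pikfyve_untreated", "pikfyve_apilimod",
                                    "null"),
                           e_max = 2.5) {
  name <- match.arg(name)
  switch(name,
    snxa_phagosome     = kinetic_profile(100, 140, 1320, 1360, e_max),
    snxa_macropinosome = kinetic_profile(120, 240, 240, 330, e_max),
    pikfyve_untreated  = kinetic_profile(60, 90, 180, 240, e_max),
    pikfyve_apilimod   = kinetic_profile(60, 90, Inf, Inf, e_max),
    null               = kinetic_profile(0, 0, 0, 0, e_max = 1)
  )
}

#' Half-max crossing times of a profile
#'
#' Closed-form arrival/departure times at the half-max level
#' `1 + (e_max - 1)/2` (or an arbitrary `level`), used as ground truth in
#' timing-recovery tests. Returns `NA` for a null profile and `Inf`
#' departure for profiles without a falling edge.
#'
#' @param profile A [kinetic_profile()].
#' @param level Crossing level; default half-max.
#' @return Named numeric vector `c(arrival, departure)` in seconds.
#' @export
profile_crossings <- function(profile, level = NULL) {
  p <- profile
  if (p$e_max <= p$baseline) return(c(arrival = NA_real_, departure = NA_real_))
  if (is.null(level)) level <- p$baseline + (p$e_max - p$baseline) / 2
  frac <- (level - p$baseline) / (p$e_max - p$baseline)
  arrival <- p$t_on + frac * (p$t_peak - p$t_on)
  departure <- if (is.finite(p$t_off)) {
    p$t_plateau_end + (1 - frac) * (p$t_off - p$t_plateau_end)
  } else Inf
  c(arrival = arrival, departure = departure)
}
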