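---
title: "Quantifying reporter dynamics on maturing phagosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reporter dynamics on maturing phagosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoflux)
```

## The measurement problem

When a *Dictyostelium* cell engulfs a yeast particle or a gulp of medium,
the resulting phagosome or macropinosome matures through an ordered
exchange of membrane lipids. Fluorescent lipid reporters — here a
PI(3,5)P2-selective sorting-nexin probe (SnxA-GFP and its tandem-PX
derivative) and PIKfyve-GFP, the kinase that produces PI(3,5)P2 — light up
the compartment membrane for a defined window of maturation. Turning such
movies into numbers requires (i) finding and following each engulfed
particle, (ii) measuring reporter intensity *at the membrane* against a
drifting cytosolic background, and (iii) summarizing arrival, persistence
and departure across events and experiments. phagoflux implements that
tool-chain, together with the two supporting biochemical quantifications
(membrane-coated-bead binding affinity; mass-photometry oligomer
fractions) and synthetic-data generators that provide full ground truth
for every stage.

## The recruitment model

Reporter fold-enrichment over time after engulfment is modelled as a
piecewise-linear trapezoid (`kinetic_profile`): baseline 1 until `t_on`, a
linear rise to `e_max` at `t_peak`, a plateau until `t_plateau_end`, and a
linear fall to baseline at `t_off`. Published traces for these reporters
are empirical; the trapezoid is the simplest shape that captures their
described rise–plateau–removal behaviour while keeping every timing
analytically accessible (`profile_crossings()` gives closed-form half-max
times, used as oracles in the tests).

The shipped presets encode the observed biology:

| preset | t_on | t_peak | plateau end | t_off | encodes |
|---|---|---|---|---|---|
| `snxa_phagosome` | 100 s | 140 s | 1320 s | 1360 s | arrival at 2 min, retained ~20 min |
| `snxa_macropinosome` | 120 s | 240 s | 240 s | 330 s | transient, peak at 4 min, gone by 5–6 min |
| `pikfyve_untreated` | 60 s | 90 s | 180 s | 240 s | arrival within 60 s, release by 4 min |
| `pikfyve_apilimod` | 60 s | 90 s | Inf | Inf | kinase inhibition blocks release (censored) |
| `null` | — | — | — | — | e_max = 1, knockout control |

Two deliberate choices. First, the phagosome preset's onset is 100 s with
a 40-s rise so that the *half-max* crossing — the package's arrival
definition — lands exactly at 120 s; "arrives at 2 min" is a statement
about when enrichment becomes visible, and half-max is the reproducible
reading of that. Second, `e_max = 2.5` is a generator choice, not a
measured value: the published axes are fold-change without absolute
magnitudes, and 2.5-fold is typical of what a bright membrane reporter
yields over cytosol with this ring geometry. All presets are plain
parameter sets and can be overridden.

## What the generator emulates — and what it does not

`generate_timelapse()` renders, per frame: a particle channel with each
yeast as a uniform disk (optionally brightening from 60 s post-engulfment
as a pHrodo acidification proxy — used only as a readout, never a
threshold), and reporter channels with uniform cytosol (default mean 100
a.u.) plus a membrane shell at each particle boundary carrying
`cytosol_mean x profile(t)`. The rendered shell is 0.65 um wide so that
the 0.2–0.55 um measurement ring sits strictly inside it even when the
detected mask is a pixel off the true boundary. Noise is additive
Gaussian (default sd 5% of the cytosol mean; acquisition SNR is rarely
reported for such movies, and 5% is a conservative spinning-disc figure)
over
optional Poisson shot noise. Defaults: 0.1 um pixels, 10-s frames,
512 x 512 fields (96 x 96 for single-event scenes).

Not emulated: the 3-D point-spread function, photobleaching, cell
motility, membrane ruffling, or debris. Passing recovery tests therefore
demonstrates that the *measurement chain* is unbiased and correctly
referenced — not that segmentation would survive every hazard of real
movies, which is why the pipeline keeps the manual review hook
(`review_events()`) that the original workflow relied on.

Scenes refuse to render particles that leave the usable field or overlap
each other: ground truth must stay unambiguous, and rejection is
preferable to silently generating unscorable data.

## Segmentation, linking, and the event unit

Segmentation thresholds the particle channel (Otsu by default; a fixed
threshold is available), fills holes, labels connected components, and
keeps objects of at least 1.5 um^2 — the size filter that separates
engulfed yeast from debris. Areas are pixel counts times `pixel_size^2`;
centroids are in um with 0-based pixel-center coordinates.

Linking uses a similarity cost combining position and size:

cost = d / (max_displacement x gap) + area_weight x |log(area ratio)|

with defaults max_displacement 2 um/frame, area_weight 1, and a gate at
cost 1.5. Matching is greedy by ascending cost: cheap, order-independent,
and — for the well-separated particles this assay produces — identical to
the exhaustive minimum-cost assignment, which the tests verify by
enumerating all assignments for up to six particles. Tracks bridging gaps
longer than `max_frame_gap` split; tracks shorter than three frames drop.
Engulfment time is never inferred: it comes from generator ground truth
or a user annotation table, mirroring the manual selection of engulfment
events in practice.

## Ring measurement and fold-enrichment

Around each detection the perimeter is enlarged into two ~0.35-um-thick
rings: an inner ring 0.2 um out (phagosomal membrane) and an outer ring
0.85 um out (bulk cytosol). One source figure legend quotes 0.3 um for
the thickness; the methods text's ~0.35 um is taken as normative, and the
value is configurable. Dilation-by-distance is implemented by
thresholding the Euclidean distance transform, so corner pixels use true
Euclidean distance rather than a structuring-element approximation; ring
areas converge on the analytic annulus as pixels shrink (tested at three
resolutions). Frames whose rings lose more than 10% of their pixels to
the image border are flagged unusable and excluded.

Enrichment at frame *t* is `inner_mean(t) / outer_mean(t)`, then
referenced to the frame nearest to (at or before) −10 s relative to
engulfment, making the trace exactly 1 at the reference. Division — not
subtraction — of the background is what makes the result exactly
invariant under detector gain, a property the tests assert to machine
precision. The ordering (background normalization first, fold-referencing
second) follows the sequential wording of the original method
description.

Cohort statistics treat the independent experiment, not the event, as the
unit: traces are averaged within experiment, then mean ± SEM is taken
across experiments; with two conditions a two-sided Welch t-test runs per
timepoint. Raw p-values are reported, as in the source assays; a
Holm-corrected column is added and labelled as an extension. A single
experiment reports SEM as absent, never zero.

## Timings, positivity and retention

`extract_timing()` reads arrival as the first half-max crossing (linear
interpolation between frames), departure as the last, and dwell as their
difference; traces ending above half-max are right-censored at the last
frame. The half-max convention is symmetric and standard; published
timings ("2 min", "4 min") are narrative and define no crossing, so one
had to be fixed.

Manual positive/negative scoring is replaced by an explicit rule:
fold-enrichment >= 1.5 sustained for >= 2 frames. At the default 5% noise
the null-profile false-positive rate of this rule is below 2% (verified
in the test suite). Retention curves bin time after engulfment (60-s
bins) and report, per bin, the fraction of events positive anywhere in
the bin among events still observed — right-censoring respected, so an
apilimod-arrested cohort correctly reads "still positive through movie
end" rather than acquiring a fictitious departure. `retention_halftime()`
summarizes a curve as the first post-peak bin below 0.5 (release time)
and the end of the last bin at or above 0.5 (censored persistence).

Pulse-chase scoring treats each field as a snapshot: vesicles are found
in the dextran channel, and the raw inner/outer ring ratio (no time
referencing — there is no pre-engulfment frame for a snapshot) is
compared to the positivity threshold. Vesicle ages at chase time `T`
(minutes after dextran addition, 2-min pulse) are uniform on
`[max(0, T - 2), T]`, which with the macropinosome preset reproduces the
observed 4-min peak in the fraction-positive curve.

## Bead binding and selectivity

Membrane-coated beads imaged at the equator are bright circles in the
membrane-dye channel. Detection thresholds that channel and accepts each
connected component as a bead when its pixels form a thin circle (radius
from the mean pixel-to-centroid distance, radial spread bounded by the
ring thickness, radius within 4–6 um for 10-um beads); touching beads
merge into a non-circular component and are rejected rather than
mismeasured. Probe intensity is the mean over an annulus on the detected
circle minus the median off-bead background.

Affinity is fit as one-site saturation,
`I(c) = nonspecific + Bmax c / (Kd + c)` — the minimal model consistent
with a single saturating titration; "apparent Kd" is kept in the naming
because avidity effects are folded into it. With experiment labels the Kd
is the mean of per-experiment fits and its error the SD across
experiments; otherwise a seeded bootstrap over beads (1,000 resamples)
supplies the error. Fits of concentration-independent controls (the
PI(5)P case) are flagged `no_binding` when Bmax is within two standard
errors of zero. On noiseless model data the fit recovers parameters to
machine precision across the 10–2,000 nM x 0.1–10 a.u. range, and the
2-SD interval covers the true Kd in >= 90% of seeded noisy titrations
(calibration test).

Lipid-array selectivity is the mean intensity of the target lipid over
the *maximum* mean among all other lipids — the conservative reading of
"x-fold preference over all other PIPs". Negative (over-subtracted) means
are clipped to a small positive floor, with a message.

## Mass photometry

Contrast-to-mass calibration is an ordinary least-squares line through
standards. Population decomposition is a Gaussian mixture fit by EM with
seeded k-means initialization and ten restarts (best likelihood kept);
the instrument vendor's analysis is proprietary, so the package uses the
textbook estimator and cross-checks it against an independent mixture
implementation in the tests. Components are returned mean-sorted (fixing
label switching), with BIC/AIC reported over k = 1–4 so the component
count can be chosen automatically. Component variances are free (widths
in the published distributions look similar, but that is not stated, so
no tying is imposed). Components with mean below ~100 kD carry a warning
flag: apparent native masses are unreliable there on this technique. The
generator's default spreads (12 kD mixture, 10 kD monomer controls) are
free choices — instrument spread is not published.

## Numerical choices and degenerate inputs

* EM convergence: relative log-likelihood change < 1e-6, <= 300
  iterations; component sd floored at 1e-4 of the data sd. Fewer distinct
  masses than components short-circuits to a reported degenerate result.
* Nonlinear fits use Levenberg–Marquardt with data-driven starts (Bmax
  from the intensity range, Kd from the half-saturation concentration);
  non-convergence is an error, not a silent NA.
* Constant images yield zero detections (not an error); all-equal
  concentrations, single-lipid panels, identical calibration contrasts,
  and annotations referencing nonexistent frames are errors.
* Ties in linking are broken by detection index, making results
  independent of input order.
* The reference frame for fold-enrichment is the nearest frame at or
  before −10 s; a trace with no pre-engulfment frame is an error asking
  for an earlier engulfment annotation.

## Problem sizes used in the shipped checks

The acceptance script regenerates everything at the reference conditions:
3 experiments x 8 concentrations x 30 beads per titration; 5,000 and
2,000 mass events; 3 fields x 40 vesicles per pulse-chase timepoint;
3 experiments x 10 phagosome events with 30-min movies; 14 untreated and
10 apilimod events. The test suite runs the same checks at reduced sizes
(e.g. 2 x 3 events, 23-min movies; 10 beads per field) chosen so the
whole suite stays fast while every tolerance is still meaningfully
exercised; all sizes are stated in the tests themselves.

## Known limitations

* Engulfment time must be supplied; the pipeline will not discover it.
* Greedy linking is not globally optimal for dense, fast-moving scenes;
  it is exact for the sparse scenes this assay produces (and verified
  against exhaustive assignment at those densities).
* The trapezoid is a first-order kinetic description; asymmetric or
  multi-phasic recruitment would need a different profile family, though
  the measurement chain downstream is agnostic to it.
* Binding is one-site by design; cooperative (Hill) or two-site models
  are out of scope, as are kinetic on/off rates.
* No 3-D rendering or PSF: resolution-limited effects on ring geometry
  (e.g. membrane signal bleeding into the outer ring for small vesicles)
  are not represented.
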