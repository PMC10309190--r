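# phagoflux

Quantification of fluorescent lipid-reporter dynamics on maturing
phagosomes and macropinosomes, for cell biologists working with
time-lapse microscopy of engulfment (e.g. PI(3,5)P2 reporters such as
SnxA-GFP, or PIKfyve-GFP, in *Dictyostelium*). The package turns
multi-channel movies into membrane-enrichment traces and recruitment
statistics, and covers the two companion biochemical assays: binding
affinity on membrane-coated beads and oligomeric-state fractions from
mass photometry. Every analysis stage has a matching synthetic-data
generator with full ground truth, so the whole chain is benchmarked by
parameter recovery.

## What it computes

**Ring-based fold-enrichment.** Engulfed particles are segmented from the
yeast channel (Otsu threshold, objects ≥ 1.5 µm²), linked across frames
by a position + size similarity cost, and tracked as phagocytic events.
Around each particle two rings are built — inner ring 0.2 µm out
(phagosomal membrane), outer ring 0.85 µm out (cytosol background), both
~0.35 µm thick — and enrichment at time *t* relative to engulfment is

```
E(t) = [ I_inner(t) / I_outer(t) ] / [ I_inner(t_ref) / I_outer(t_ref) ],   t_ref = −10 s
```

which is exactly 1 at the reference frame and invariant to detector gain.

**Kinetics.** Arrival/departure are half-max crossings of the trace
(linear interpolation), dwell their difference, with right-censoring at
movie end. An explicit positivity rule (≥ 1.5-fold for ≥ 2 frames)
replaces manual scoring, and retention curves report the proportion of
events positive per time bin. Cohort statistics use the experiment as
the unit (mean ± SEM over experiments, per-timepoint Welch t-tests).

**Binding affinity.** Beads are detected as equatorial circles in the
membrane-dye channel; probe intensity per bead (background-subtracted
ring mean) is fit to one-site saturation
`I(c) = NS + Bmax·c/(Kd + c)` for the apparent Kd, with errors from
per-experiment SD or a seeded bead bootstrap.

**Mass photometry.** Contrast-to-mass calibration by OLS against
standards; event-mass distributions decomposed into Gaussian populations
by seeded EM with k-means restarts, mean-sorted, with BIC across k = 1–4.

## Worked example

Simulate one phagocytic event with the phagosome reporter preset and run
the full measurement chain:

```r
library(phagoflux)
library(dplyr)

scene <- single_event_scene(profile_preset("snxa_phagosome"),
                            movie_min = 5)
tl <- generate_timelapse(scene, seed = 1)

dets <- purrr::map_dfr(seq_len(tl$n_frames) - 1, function(f) {
  d <- segment_particles(tl$stack[, , 1, f + 1], tl$pixel_size)
  d$frame <- f
  d
})
events <- build_events(dets,
  engulfment = tl$ground_truth$particles$engulfment_frame[1])
trace <- fold_enrichment(measure_event(tl, events))
extract_timing(trace)
#> # A tibble: 1 × 7
#>   t_arrival t_peak t_departure dwell peak_value censored positive
#>       <dbl>  <dbl>       <dbl> <dbl>      <dbl> <lgl>    <lgl>
#> 1      120.    190         290  170.       2.51 TRUE     TRUE
```

The reporter crosses half-maximum 120 s after engulfment (the preset's
2-min arrival), reaches ~2.5-fold enrichment, and is still on the
membrane when this short movie ends (`censored`), so the 170-s dwell is
a lower bound. A titration fit looks like:

```r
pts <- purrr::map_dfr(c(10, 50, 200, 800, 2000), function(cc) {
  bf  <- generate_bead_field(187.3, conc = cc, n_beads = 10, seed = 1)
  det <- segment_bead_rings(bf$membrane, bf$pixel_size)
  measure_bead_probe(bf$probe, det, bf$pixel_size) |>
    mutate(conc_nM = cc)
})
fit_binding(pts)
#> <pf_binding_fit> apparent Kd = 187.3 +/- 3.64 nM, Bmax = 0.9654, NS = 0.0006237
```

`autoplot()` methods exist for binding fits, mass fits and selectivity
results; `plot_trace_cohort()` and `plot_retention()` draw the cohort
summaries. YAML-driven wrappers (`run_simulate()`,
`run_phagosome_pipeline()`, `run_binding_pipeline()`,
`run_mass_pipeline()`) tie the stages into reproducible runs with fixed
CSV schemas and a config-hashed manifest.

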