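# calcitrace

Quantitative analysis of stimulus-evoked cytoplasmic calcium transients in
cultured neurons, plus intensity-threshold classification of immunostained
cells — with a seeded synthetic-data generator so the whole pipeline is
testable without recordings.

## Who this is for

Labs that image calcium-indicator-loaded neurons with a fast camera
(~100 frames/s) while delivering field-stimulation pulses, and that need
the standard dendritic readouts computed reproducibly: ΔF/F₀ traces from
small dendritic ROIs or single pixels, per-pulse peak amplitudes, decay
time constants, cumulative calcium load over a train, subcellular
gradients, responder fractions, and cell-type proportions from
immunofluorescence.

## The model and statistics at the core

Raw stacks are converted as ΔF/F₀ = (F − F₀)/F₀ after subtracting the
averaged shutter-closed (dark) frames, where F₀ is the pixelwise mean over
the 1 s preceding the first stimulus. For each stimulus at time *t₀*, the
transient falls as

  F(t) = a · exp(−t/τ),

fitted without constraints from the last crossing of 80% of the peak
amplitude to the first crossing of 20%; fits with r² < 0.990 are rejected.
Peaks are detected when a 15 Hz-filtered trace crosses 5 × RMS noise (RMS
measured −1000…−104 ms before the first pulse); decay fits use a 5 Hz
filter. Cumulative load after pulse *k* is ∫|ΔF/F₀| from the first
stimulus to 1 s after pulse *k*. Two closed forms summarize what a τ
change means: Area(∞) = τ for a unit-peak decay, and the time above a
fractional threshold, T = τ·ln(1/threshold).

For immunostaining, somatic intensity (max of a 7-pixel running average
along a line through the soma) is regressed on log₁₀ somatic area over
negative-control cells, and the upper limit of the 95% simultaneous
(Working–Hotelling–Scheffé) confidence band,

  ŷ(x) ± √(2·F₀.₉₅(2, n−2)) · SE(ŷ(x)),

is the marker-positivity threshold. Group comparisons use two-tailed
Student's t-tests on log-transformed data.

## Worked example

Simulate one neuron, run the full train analysis, then fit a single-pulse
decay:

```r
library(calcitrace)

geom  <- make_geometry(seed = 11)                       # soma 263 um^2, 2 dendrites
prot  <- stimulus_protocol(n_pulses = 10, frequency = 1,
                           pre_window = 2, post_window = 2)
stack <- simulate_stack(geom, kinetics_params(amplitude_a = 0.5, tau = 2),
                        prot, noise_params(read_noise_sd = 2, seed = 11))

sub   <- subtract_dark(stack)
dff   <- compute_dff(sub, compute_f0(sub, prot))
rois  <- place_rois(geom, dendrite_id = 1)
trace <- extract_roi_trace(dff, rois)
m     <- transient_metrics(trace, prot)
round(m[, c("pulse", "amplitude", "tau", "r_squared", "cumulative_load")], 3)
#>    pulse amplitude   tau r_squared cumulative_load
#> 1      1     0.527 5.348     0.110           0.419
#> 2      2     0.502 1.120     0.807           1.084
#> 3      3     0.474 0.614     0.980           1.901
#> ...
#> 10    10     0.476 0.438     0.970           8.890
```

Each pulse adds ~0.5 ΔF/F₀ above its local baseline (the simulated
amplitude), and cumulative load grows by ~1 ΔF/F₀·s per 1-Hz pulse. The
per-pulse decay fits are truncated by the next pulse and noisy, which is
exactly what the r² ≥ 0.990 acceptance rule is for (`tau_valid` is FALSE
for these rows); later pulses also show the faster apparent τ expected
when transients ride on the preceding tail. A single pulse gives the clean
fit:

```r
prot1 <- stimulus_protocol(n_pulses = 1, pre_window = 2, post_window = 8)
stack <- simulate_stack(geom, kinetics_params(amplitude_a = 0.5, tau = 2),
                        prot1, noise_params(read_noise_sd = 2, seed = 11))
sub   <- subtract_dark(stack)
dff   <- compute_dff(sub, compute_f0(sub, prot1))
tr5   <- filter_trace(extract_roi_trace(dff, place_rois(geom, 1)), 5)
rms   <- compute_rms(tr5, prot1)
pk    <- detect_peaks(tr5, prot1, rms)
fit   <- fit_decay(tr5, pk[1, ])
#> RMS noise: 0.0053  |  peak amplitude: 0.518 dF/F0
#> tau = 2.046 s (r^2 = 0.9957, accepted = TRUE)
decay_impact(fit$tau, threshold = 0.2)
#> area under unit-peak decay = 2.046 s; time above 20% = 3.293 s
```

The recovered τ matches the simulated 2 s within a few percent, and the
decay-impact identities convert it into total area and supra-threshold
time. See the vignette (`vignettes/calcium-transient-analysis.Rmd`) for
the full account of the methods, conventions, and the classification
workflow (`simulate_immuno`, `fit_band`, `classify_cells`,
`population_summary`, `responder_fraction`).

A command-line wrapper with `simulate | analyze | classify | report`
subcommands is installed at `inst/scripts/calcitrace`.

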