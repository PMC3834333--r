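---
title: "Quantifying stimulus-evoked calcium transients and classifying immunostained neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stimulus-evoked calcium transients and classifying immunostained neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitrace)
```

## The measurement problem

Cultured striatal neurons loaded with a fluorescent calcium indicator and
depolarized by brief field-stimulation pulses show a stereotyped response in
their dendrites: cytoplasmic calcium rises within tens of milliseconds of
each pulse and then decays over seconds. Imaged with a fast camera
(100 frames/s, 14-bit, 1.18 µm pixels), this response is a proxy for
intrinsic excitability, and its quantitative features — peak amplitude,
decay time constant, cumulative load over a stimulus train, subcellular
gradients, and the fraction of neurons responding at all — are the readouts
this package computes. A companion problem is knowing *which* cells were
measured: striatal cultures are a mixture of GABAergic medium spiny neurons
(MSNs), GABAergic interneurons and rare large cholinergic interneurons, and
the package classifies immunostained cells into these types from somatic
staining intensity.

Every stage is driven by, and testable against, a seeded synthetic-data
generator, so no recordings are required to validate the pipeline.

## From raw counts to ΔF/F₀

The preprocessing model is deliberately minimal and matches standard
practice for EMCCD recordings:

1. **Dark subtraction** (`subtract_dark`). Shutter-closed frames are
   averaged pixelwise and subtracted from every frame. Negative values are
   kept: clipping at zero would bias the baseline upward at dim pixels.
2. **Baseline** (`compute_f0`). F₀ is the pixelwise mean over the 1 s
   immediately preceding the first pulse. No photobleach correction is
   applied anywhere in the pipeline; the baseline is assumed stable over
   the pre-stimulus window, which the generator honors by construction.
3. **Normalization** (`compute_dff`). ΔF/F₀ = (F − F₀)/F₀, computed in
   double precision throughout. Pixels with non-positive F₀ carry no signal
   (background, dark residue) and are marked invalid rather than producing
   spurious ratios. F₀ is never recomputed inside a train: per-pulse
   baselines are handled downstream at the trace level (see below).

**Temporal filtering** (`gaussian_smooth`, `filter_trace`). Traces are
smoothed with a Gaussian kernel whose −3 dB point equals the stated cutoff:
σ_t = √(ln 2)/(2π f_c), i.e. σ_t ≈ 8.8 ms at 15 Hz and ≈ 26.5 ms at 5 Hz.
This mapping from "filtered at f Hz" to a kernel width is a convention
choice — analysis programs do not document theirs — so it is centralized in
one function and recorded by callers. Edges are replicate-padded, making
the DC gain exactly 1; the realized −3 dB point is verified by FFT-style
measurement in the tests. Detection runs on 15 Hz-filtered traces, decay
fitting on 5 Hz.

## ROIs, pixel paths, and traces

Dendritic measurements average 12 pixels: three contiguous 2×2-pixel ROIs
placed end-to-end along the dendrite centerline, with the most proximal
pixel 6 pixels (~7 µm) from the soma–dendrite border. Distances are
measured **along the centerline**, not as Euclidean chords, which is what
traversing a curved dendrite means in practice. A dendrite is *rejected*
(a result, not an error) when it is ≤ 12 pixels long, when the 2-pixel ROI
extent exceeds its width, or when a ROI would sit on an annotated branch
point; with synthetic geometry the annotations come from the generator, and
with real data from a user-supplied mask — the package does not attempt
branch detection or dendrite tracing. Because all ROIs have equal pixel
counts, averaging ROIs and averaging pixels coincide. ΔF/F₀ values are
averaged, never raw counts: ROI averaging commutes with the F₀ ratio only
for pixel-uniform baselines, and dendritic baselines are not uniform.

Single-pixel analysis (`pixel_path`, `extract_path_traces`) follows an
ordered 8-connected path from the nucleus center through the soma into a
dendrite, one unaveraged trace per pixel, each tagged with its anatomical
label and position.

## Transient metrics

**Noise floor.** RMS noise is the root-mean-square deviation about the
window mean over the fixed window −1000…−104 ms before the first pulse
(`compute_rms`).

**Detection** (`detect_peaks`). For each pulse the search window runs from
that pulse to the next (1 s past the last pulse). The window maximum is a
peak when it crosses the pre-stimulus mean + 5×RMS. The amplitude of a
detected peak is measured against a **local baseline**: the trace value
104 ms before the pulse. Two choices deserve explanation:

* *Why 104 ms ahead and not the sample immediately before the pulse?* The
  Gaussian kernels smear each rise backwards by up to ~4σ (≈ 106 ms at
  5 Hz); a baseline sample inside that support would already contain the
  next transient. 104 ms is the same offset at which the RMS window ends,
  so both baseline conventions clear the kernel support together. The cost
  is a slight (e^{0.104/τ}) overestimate of a decaying tail, < 6% for
  τ ≥ 2 s.
* *Local vs global baseline.* With the local baseline, train amplitudes
  are per-pulse increments; `baseline_mode = "global"` refers all
  amplitudes to the pre-train level instead. Both are provided because
  train amplitudes can be defined either way; the local convention is the
  default.

A trace with no detected peak across the train is a non-responder.

**Fixed-window amplitude** (`peak_amplitude_simple`). When transients may
be absent (channel blockade, single-pixel profiles) amplitude is simply the
highest point 10–70 ms after the pulse minus the F₀ baseline, with no
threshold.

**Decay fitting** (`fit_decay`). A single exponential a·e^{−t/τ} is fitted,
unconstrained, to the segment from the **last** crossing of 80% of the peak
amplitude to the **first** crossing of 20% (crossings by linear
interpolation; the last/first rule resolves multiple noise crossings).
Time is referenced to the peak, so the fitted a estimates the amplitude at
the peak. The fit is initialized from a log-linear regression and refined
by Levenberg–Marquardt; r² = 1 − SS_res/SS_tot on the fitted segment, and
fits with r² < 0.990 are flagged invalid and excluded from summaries. A
segment that never reaches 20% before the next pulse is fitted as-is and
flagged `truncated`.

One behavior worth knowing: when train responses superpose, the decaying
tail of earlier pulses acts as a slowly-shrinking offset under later
segments, so per-pulse fits with a local baseline report progressively
*faster* apparent τ across a train. This is a property of the measurement
convention, not a bug — the tests pin it down — and it mirrors the decay
acceleration commonly reported for later pulses in 1-Hz trains.

**Cumulative load** (`cumulative_load`). For pulse k, the integral of
|ΔF/F₀| from the first stimulus onset to 1 s after pulse k, by the
rectangle rule at the frame interval, with no normalization (units:
ΔF/F₀·s, i.e. arbitrary units). For a unit-amplitude transient the
closed forms Area(∞) = τ and T = τ·ln(1/threshold) (`decay_impact`) give
the impact of a τ change, and ratios of either quantity between conditions
reduce to the ratio of the τs.

## Spatial profiles

`profile_from_path` computes, per pixel, the fixed-window amplitude and the
baseline F₀ normalized to the **profile's maximum** (the proximal end in
practice; per-profile max was chosen over the somatic value because it is
defined even when the path omits the soma, and it is flagged in the
output). `compare_profiles` reports per-position group means ± SEM and
two-tailed t-tests on log-transformed amplitudes (raw-scale when a position
contains non-positive values, flagged in `log_used`). Positions are not
multiplicity-corrected by default, mirroring per-parameter testing
practice; a Benjamini–Hochberg option exists. "Local discrete peaks during
the decay phase" are operationalized as secondary local maxima rising
≥ 5×RMS above the running minimum since the main peak — a deliberately
simple rule, since their absence is a qualitative observation.

## Immunofluorescence classification

Somatic staining intensity is the maximum of a 7-pixel running average
along a line through the soma center (`somatic_intensity`). Because
negative-control intensity grows with cell size, the positivity threshold
is not a constant: intensity is regressed on log₁₀ somatic area over
negative-control cells (primary antibody omitted, pooled across
genotypes), and the **95% uniform confidence band** of that regression is
computed as the Working–Hotelling–Scheffé simultaneous band,
halfwidth(x) = √(2·F₀.₉₅(2, n−2)) · SE(ŷ(x)). This band covers the entire
mean control line with 95% probability regardless of area — the property
verified by Monte-Carlo in the tests via the exact quadratic-form
criterion (`band_contains_line`). The upper limit is the threshold; a cell
is positive only when its intensity **strictly exceeds** it (ties are
negative); the lower limit is computed but unused. One band is fitted per
marker channel, since imaging conditions differ per fluorophore.

Cell types follow the marker logic of these cultures: MSN = GAD65⁺ ∧
DARPP-32⁺; GABAergic interneuron = GAD65⁺ ∧ DARPP-32⁻; cholinergic =
(GAD65⁻ ∨ VGAT⁻) ∧ VAChT⁺; anything else, or a missing required channel,
is unclassified. Somatic size separates cholinergic cells almost perfectly
in practice, but size is deliberately never a classifier input — calls are
intensity-only. `population_summary` tabulates proportions inside the
158–537 µm² area gate (the range over which calcium responders occur), and
`responder_fraction` derives its size gate from the smallest responder of
the reference group.

Because the band bounds the *mean* control line, not individual control
cells, an antigen-negative channel whose intensity is drawn from the same
distribution as the controls still exceeds the threshold with appreciable
probability (~40% at n = 100 controls). With bright positives this barely
affects marker sensitivity, but it caps per-cell class agreement below
100% — mostly GABAergic interneurons picking up DARPP-32 false positives.
At realistic sample sizes (~120 cells/genotype) the resulting flow is well
inside binomial sampling error of the class fractions, which is what the
acceptance checks assert; this is an honest property of the thresholding
method itself.

## The synthetic-data generator

The generator produces exactly the statistical structure the analysis
assumes, with ground truth attached:

* **Geometry** (`make_geometry`): disc soma with area uniform in
  158–537 µm² (the responder range), nucleus at 45% of the somatic radius,
  straight 8-connected dendrites ≥ 13 pixels beyond the border, widths
  ~2.8–3.6 µm tapering to 80% distally. Pixel pitch 1.18 µm, frame
  interval 10 ms by default; both configurable.
* **Kinetics** (`kinetics_params`): instantaneous rise at each pulse (the
  real rise of a few tens of ms is never used by the analysis) and
  single-exponential decay. Amplitude grows and F₀ falls linearly with
  dendritic distance (defaults +2%/px and −1%/px), the nucleus is silent
  and the somatic cytoplasm responds at 10% — the subcellular gradients the
  spatial module must recover. Train peaks either superpose (default) or
  top up to an absolute ceiling; the mode is recorded in metadata because
  recordings do not distinguish the two conventions. An optional per-pulse
  τ multiplier schedule injects decay acceleration when a study needs it
  as ground truth.
* **Noise** (`noise_params`): dark offset + Gaussian read noise + Poisson
  shot noise on the scaled intensity — the standard EMCCD abstraction.
  With shot noise off and zero read noise the stack equals the analytic
  model to ≤ 1e-9, which the recovery tests exploit. ≥ 20 dark frames are
  emitted alongside.
* **Immunostaining** (`simulate_immuno`): class labels from the
  (0.95, 0.04, 0.01) mixture, areas log-uniform (cholinergic cells in
  their own larger 600–850 µm² range), each channel = background line
  (−200 + 150·log₁₀area, SD 30 a.u.) with antigen-positive channels ×5.
  Negative controls carry pure background.

What the generator does **not** emulate — optics/PSF, photobleaching,
motion, cell-to-cell crosstalk, nonstationary noise — bounds what passing
tests show about real recordings: the pipeline is validated as a correct
implementation of the measurement model, not as robust to artifacts the
model excludes.

## Study conditions used by the simulation checks

The trace-level checks fix, once, a set of conditions representative of
these recordings: reference amplitude a = 0.5 ΔF/F₀ with lognormal
between-dendrite variability (sdlog 0.25, ≈ 25% CV), τ = 2 s, additive
trace noise SD 0.02 ΔF/F₀ (the residual after 12-pixel averaging, before
filtering), 10 pulses at 1 Hz, groups of n = 84 dendrites, and a +15%
amplitude effect for the comparison group. Under these conditions the
per-pulse log t-test on cumulative load is significant at pulses 2–10 in
well over 80% of 200 replicate experiments and recovers the ~15% load
increase; noisy decay fits recover τ with ~2% median error over 500
dendrites; pure-noise traces trigger the 5×RMS detector in ≤ 1% of
windows; and 10⁴ simulated control populations of 100 cells put the true
background line inside the 95% band 95% ± 1% of the time. Band-fit checks
use n = 100 controls and mixtures of 120 cells per genotype, the scale of
the tabulated counts.

## Limitations

* Single-exponential decays only; no multi-exponential fitting or spike
  inference.
* Dendrites within a neuron are treated as independent units in group
  statistics, replicating the field's convention rather than endorsing it;
  no mixed-effects modeling.
* No multiple-testing correction across the ten per-pulse tests by
  default (an option exists for spatial profiles).
* The proprietary heuristics of commercial event-detection software are
  not reproduced beyond the documented rules (RMS window, 5×RMS threshold,
  80→20% fit, r² < 0.990 rejection).
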