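---
title: "Analysing spontaneous activity in trigeminal ganglion explants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spontaneous activity in trigeminal ganglion explants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tgcalcium` analyses ex vivo calcium-imaging sessions of neonatal
trigeminal ganglion (TG) explants expressing the slow, sensitive calcium
indicator GCaMP6s. A typical session images a 660 × 660 µm locus of the
whisker-innervating region at 1 Hz for 10 minutes (600 frames), split
into 5-minute blocks, sometimes ending in a high-potassium depolarising
epoch that verifies tissue viability. The pipeline answers the questions
such recordings pose: which somata fire spontaneously, how often and
with what transient kinetics, whether firing is correlated between
neurons and whether correlated pairs sit close together, and how the
firing population is composed of small- (SD, < 20 µm), medium-
(MD, 20–25 µm) and large-diameter (LD, > 25 µm) neurons.

Every stage is driven and validated by a ground-truthed synthetic-movie
generator, so the package is fully testable without any recorded data.

## The processing model

The stages run in a fixed order (wrapped by `run_pipeline()`), each
available as a standalone function:

1. **Bleach correction** (`bleach_correct`). Photobleaching is modelled
   as a global multiplicative monoexponential. The default fits
   `a·exp(-t/τ) + c` to the frame-mean series and divides it out
   (normalised to the first frame); a simple-ratio fallback rescales
   each frame to the first frame's mean when the fit does not converge.
2. **Rigid motion correction** (`motion_correct`). Per-frame integer
   translation against the movie mean (or first frame) by FFT phase
   correlation. Shifts larger than 25 % of the frame are treated as
   estimation failures: the frame is flagged and left unshifted.
3. **Frame quality control** (`drop_bad_frames`). Frames with large
   estimated motion or whole-field intensity jumps (measured against a
   running median of frame means, insensitive to slow bleaching) are
   *flagged*, never deleted, so frame indices stay aligned with the 1 Hz
   timestamps; traces interpolate linearly across them. More than 20 %
   flagged frames is a hard error.
4. **ROI detection** (`detect_rois`). Activity-based: the temporal
   standard-deviation image highlights transient pixels; it is
   Gaussian-smoothed, thresholded, watershed-segmented, filtered by
   equivalent-circle diameter, and touching fragments whose traces
   correlate above 0.95 are merged. Curated or ground-truth ROI sets can
   always be substituted (`roi_set_from_circles`), and downstream stages
   cannot tell the difference.
5. **Refinement** (`refine_rois`). An automated surrogate for manual
   trace inspection: ROIs with no detectable transients or peak ΔF/F₀
   below a floor are removed with a log.
6. **ΔF/F₀ and events** (`compute_dff`, `detect_peaks`). Sliding
   60-frame baseline; PeakCaller-style transient detection and
   parametrization (below).
7. **Correlation analysis** (`thresholded_signal`,
   `pairwise_correlation`, `pair_records`, `classify_pairs`). All-pairs
   Pearson r on supra-threshold ΔF/F₀, Euclidean inter-centroid
   distances, the r > 0.5 correlated-pair rule, and a two-sided
   Mann–Whitney comparison of the two distance distributions.
8. **Population summaries** (`count_active`, `percent_active`,
   `classify_soma`, `subtype_composition`,
   `estimate_subtype_activity`, `compare_groups`,
   `before_after_summary`) and **rendering**
   (`render_temporal_map`).

## ΔF/F₀ and the firing thresholds

The baseline F₀ at frame *t* is the mean raw fluorescence over a
60-frame window and `dff = (F - F0)/F0`. The window alignment is
**trailing** by default (the window ends at *t*): it is causal, uses no
future frames, and behaves sensibly at a drug-application boundary. A
centred alignment is available; edges truncate the window either way.

Two threshold rules are used, both computed over the whole trace:

* `mean_plus_sd` — mean(ΔF/F₀) + SD; the spontaneous-activity rule used
  for rasters and for selecting supra-threshold signal in the
  correlation analysis;
* `ten_sem` — 10·SD/√n; the stricter rule used for the high-potassium
  binary heatmaps (`high_k_response`).

Whether these statistics should be taken over the whole trace or only a
baseline segment is ambiguous in the source protocol; whole-trace is
implemented and documented, and is what the tests assume.

## Transient detection and parametrization

`detect_peaks` follows the PeakCaller recipe. The ΔF/F₀ trace is
smoothed with a Savitzky–Golay filter and an underlying trendline is
computed as a two-sided exponential moving average (the mean of a
forward and a backward first-order EMA). A local maximum of the
smoothed trace is accepted as a transient iff

* (a) its smoothed value exceeds the firing threshold,
* (b) within 30 frames before it (`max_lookback`) the trace was at
  least 20 % (`required_rise_pct`) of its height-above-trendline lower,
  and
* (c) within 25 frames after it (`max_lookahead`) it falls by at least
  15 % (`required_fall_pct`) of that height. If the trace ends before
  the look-ahead window completes, the event is kept with a missing
  decay time — which is why sessions report slightly fewer decay times
  than amplitudes.

Rise time is peak minus onset (the last pre-peak frame at or below the
rise level), decay time is the first post-peak frame at or below the
fall level, duration is their sum. Peak parameters are read **from the
raw ΔF/F₀**, not the detrended trace: the amplitude is the maximum
unsmoothed ΔF/F₀ within half a smoothing window of the detected peak.
The trendline feeds only the rise/fall percentage criteria.

Numerical defaults that the protocol leaves open, chosen once:

* Savitzky–Golay window 9, order 3. A 1 Hz GCaMP6s transient
  (rise τ ≈ 1.5 s, decay τ ≈ 4 s, full width ≈ 8 frames) survives this
  smoothing; a window of 7 leaves secondary noise maxima on decay tails
  that cost precision at realistic signal-to-noise, while 9 holds both
  sensitivity and precision above 0.9 at event SNR 5.
* EMA smoothing factor α = 0.05, slow enough that the trendline tracks
  drift rather than the transients themselves.
* Rise/fall percentages are interpreted as percentages of the peak's
  height above the trendline.

The detector is verified against a literal brute-force enumerator (an
independent loop implementation of (a)–(c)) on hundreds of random
traces; the two must agree event-for-event.

## Correlation analysis choices

"Only transients exceeding the threshold" enter the correlation: frames
below the `mean_plus_sd` threshold are zeroed and supra-threshold
frames keep their ΔF/F₀ value, preserving amplitude information (a
binarized variant is available via `thresholded_signal(..., binary =
TRUE)`). Never-firing (zero-variance) signals are excluded from pair
records by default, since ROI sets are placed on spontaneously firing
neurons. A pair is *correlated* iff r > 0.5 strictly; r = 0.5 is
non-correlated. Distances use the plain Euclidean formula on µm
centroids, with coordinates 0-based at the top-left pixel centre — one
convention used everywhere, including rendering and the distance
formula.

The Mann–Whitney U test reports the U of the first sample. Both groups
≤ 8 with no ties: exact two-sided p by complete enumeration of all
group assignments; otherwise the normal approximation with tie and
continuity correction. The published comparisons (thousands of pairs)
only ever need the approximation; the exact path exists so small test
fixtures have exact behaviour. Note that rank statistics have an
attainable p floor: at n = m = 10 the approximation cannot go below
roughly 2.6 × 10⁻⁴ however separated the groups are.

## Population statistics

Soma classes partition the positive diameters with both boundaries
closed into MD (20 µm → MD, 25 µm → MD), matching the "20–25 µm"
convention. The subtype active-fraction estimator is

> est_active % = overall_active % × share_active % / share_all %,

reported to the nearest integer. With the published inputs
(12.3 % overall; SD 17.1/67.3, MD 39.5/27.3, LD 43.4/5.5) it yields 3 %,
18 % and 97.06 % for SD, MD and LD; the LD value is reported as
computed rather than forced to a looser rounding.

`compare_groups` exposes the four designs used for stage comparisons
(one-way ANOVA + Tukey, Kruskal–Wallis, Mann–Whitney, paired two-tailed
t) with the significance-star convention \* p < 0.05, \*\* p < 0.005,
\*\*\* p < 0.001, \*\*\*\* p < 0.0001. A Shapiro–Wilk normality check
per group is reported as a diagnostic but never switches the design:
reproducibility over automation.

## What the synthetic generator emulates

`simulate_movie(sim_config(...))` renders circular somata placed
without overlap in the field, each with baseline fluorescence 100 over
background 20 (arbitrary units). Active neurons receive Poisson-timed
transients with the unit-peak difference-of-exponentials kernel
`(1 - e^(-t/rise τ))·e^(-t/decay τ)`; the movie is multiplied by a
global bleach `e^(-t/bleach τ)`, optionally jittered by rigid integer
shifts, and Gaussian noise is added. A single master seed drives
per-neuron substreams, so rendering is bit-reproducible.

Defaults encode the neonatal (P4–P6) study conditions: 660 µm field,
600 frames at 1 Hz, 300 neurons, 12.3 % active, SD/MD/LD weights
0.673/0.273/0.054 with class means 16.5/22.5/28 µm (anchored on
measured marker-positive diameters of ~18.1 µm for nociceptor-like and
~26.4 µm for mechanosensory-like populations), event rate 1/min per
active neuron (so nearly every active neuron fires within a 5-min
block), rise τ 1.5 s and decay τ 4 s (GCaMP6s-like at 1 Hz), bleach
τ 600 s, noise SD 0.05 of baseline. Correlated pairs are emulated by
shared onset times with ≤ 1 frame of independent jitter and at most a
quarter of private events, placed within a configurable distance —
which produces Pearson r > 0.5 on thresholded ΔF/F₀ at 1 Hz without
asserting a mechanism. An optional `event_epoch` confines onsets to a
frame range, which is how drug-blockade sessions are emulated; an
optional `high_k_start_frame` adds a sustained global activation.

What it deliberately does **not** emulate: optics (no point-spread
function, no depth attenuation), indicator biophysics (no saturation or
facilitation), overlapping somata, non-rigid tissue deformation, or
correlated noise. Passing tests therefore demonstrate that the
algorithms recover the statistical structure they claim to measure —
not that they are robust to every artefact of real microscopy.

## Degenerate inputs and tie-breaks

* Constant movies pass through bleach correction unchanged; a constant
  trace has threshold 0 and zero events; an all-tied Mann–Whitney
  reports p = 1.
* Blank noise: ROI detection adds a robust noise floor
  (median + 6 MAD of the smoothed SD image) to the activity-percentile
  threshold, and nuclei counting demands real foreground/background
  contrast before counting, so noise-only images yield zero ROIs /
  count 0 rather than speckle.
* Plateau local maxima: the first frame of a plateau is the peak.
* Zero-variance groups in `compare_groups` are reported as degenerate,
  never crashed on.
* A zero firing threshold (a trace with no variability at all) yields
  an all-zero high-potassium heatmap rather than an all-ones one.

## Problem sizes used by the test-suite

The bundled tests simulate sessions between 100 × 100 px × 150 frames
(unit tests) and the full 220 × 220 px × 600 frames, 300-neuron
neonatal session (the end-to-end recovery check), with nuclei fixtures
up to 440 × 440 px and 300 nuclei. At 3 µm/px the full session is an
~230 MB double array; the whole suite completes in about a minute on a
single CPU.

## Known limitations

* Motion correction is rigid and integer-pixel; sub-pixel registration
  and non-rigid deformation are out of scope.
* ROI detection is activity-based: silent neurons are invisible to it
  by design (total population counts come from nuclei stills), and
  overlapping somata are not demixed.
* No spike inference: transients are described, not deconvolved.
* TIFF metadata is written to a JSON sidecar (the bundled TIFF writer
  cannot emit description tags); ImageJ description tags are still
  parsed on read.
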