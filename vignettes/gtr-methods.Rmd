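---
title: "Quantifying the glabellar tap reflex from video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the glabellar tap reflex from video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrflex)
```

## The measurement problem

The glabellar tap reflex (GTR) is a brain-stem blink reflex elicited by a
light tap between the eyebrows. Healthy adults habituate after a few taps;
patients with idiopathic Parkinson's disease (iPD) typically keep blinking,
and their spontaneous (non-reflex) blinking changes in rate and duration.
`gtrflex` quantifies both phenomena from a high-framerate facial video
(at least 180 frames/s; 5.6 ms between images) and a 468-point face-mesh
landmark stream, without electrodes.

The package assumes:

* a single face, filmed at roughly 45°, with a uniformly sampled frame
  stream (timestamps are validated to 1 µs of uniformity);
* an external landmark provider per frame — a face-mesh model, a recorded
  landmark file, or the built-in synthetic generator. Landmarks stay in
  normalised coordinates and become pixels only inside ROI construction,
  so streams are resolution independent;
* the examiner taps with a blue glove, so glove contact raises the mean
  blue intensity over the glabella.

## From pixels to events

**Signals.** The tapping channel is the arithmetic mean of blue-channel
intensities over the glabellar polygon (medial-brow/midline landmark
diamond by default; the index set is configuration because it is
mesh-version dependent). The blinking channel counts non-zero pixels inside
the eyelid-contour-masked eye bounding box and inverts the count as
`max(count) − count`: closure shrinks the lid contour, so blinks become
positive peaks on a near-zero open-eye baseline. Of the two readings of
"inverted" (negation vs. max-minus-count), max-minus-count is used because
it directly yields a positive-amplitude signal; after baseline removal the
two differ only by a constant. Frames with no detected face are explicit
gaps: the affected samples are linearly interpolated (bounded by their
neighbours) before conditioning, and their ROIs reuse the last valid
geometry, rather than being silently dropped and corrupting the uniform
sampling assumption.

**Conditioning.** Order is fixed and enforced: raw → baseline-removed →
filtered. Baseline removal subtracts a running 10th percentile over a
centred 2 s window (forced to an odd sample count so the centre is
unambiguous; the window should stay longer than three times the longest
expected event). Percentile tracking follows illumination drift while
leaving upward peaks essentially intact — a constant signal maps exactly to
zero. The low-pass filter is a 4th-order Butterworth applied
forward-backward (zero phase), so event peak times are not shifted — this
matters because blink classification hinges on a ±millisecond window. Two
passes square the magnitude response, giving gain 0.5 at the cutoff.

Two numerical details of the filter are worth recording. At the default
0.75 Hz cutoff and 180 Hz sampling the normalised cutoff is 0.008, and
start-up transients last seconds; the implementation therefore extends the
signal by even (mirror) reflection at both ends and starts each pass from
the steady state of its first sample, so transients decay inside the pads.
Mirror rather than point reflection is used because point reflection about
a single endpoint sample of an oscillating signal displaces the pad's mean
by twice the instantaneous oscillation — the low-pass then faithfully tracks
that spurious level into the record.

The 0.75 Hz cutoff (chosen in the source protocol to suppress illumination
flicker) is applied to both channels by default but is configurable per
call: it materially widens 0.1–0.2 s blinks, so width-recovery validation
runs at a 10 Hz cutoff, which passes the blink band while still removing
25 Hz flicker essentially completely.

**Events.** Taps and blinks are local maxima whose topographic prominence
(height above the higher of the two minima separating the peak from higher
terrain) exceeds a fraction of a reference scale — 0.3 for taps, 0.2 for
blinks. The reference is the larger of the robust signal range (5th–95th
percentile) and the largest single-peak prominence: signals whose events
occupy under ~5 % of samples collapse the robust range, and the ringing
sidelobes that a sharp low-pass leaves around a large isolated event would
otherwise pass a threshold anchored to it. Peaks closer than the minimum
separation (0.4 s taps, 0.1 s blinks) are thinned, keeping the higher
prominence, the earlier on an exact tie.

Blink duration is the width at half prominence, with crossings located by
linear interpolation between bracketing samples and clipped at the
prominence bases. The reported event time is the centre of the
half-prominence interval. For a symmetric pulse this equals the apex; it is
far more robust than the raw argmax on flat-topped pulses — the filtered
glove-contact trapezoid is flat at the scale of its ~0.15 s contact, and
pixel quantisation flattens wide blink tops, where argmax jitter of tens of
milliseconds would otherwise leak into tap timing.

**Classification.** A blink whose apex lies in the closed interval
`[tap − 50 ms, tap + 200 ms]` is a reflex blink of that tap; both
boundaries are inclusive since the window's verbal definition carries no
open/closed language and the choice only affects measure-zero cases.
Overlapping windows (impossible under the < 2 taps/s protocol, handled for
robustness) resolve to the nearest tap, earlier on a tie. Every other blink
is assigned as non-reflex to the last tap before it; blinks after the final
tap count in the final tap's bin, matching the reference tables, and blinks
before the first tap form a separate `pre_first_tap` category excluded from
the tap-indexed tables and width averages. The apex (not onset or
half-rise) carries the classification, since peaks are the detected
entities.

## Statistics

Group summaries are arithmetic means with the sample (n−1) SD; `NaN` marks
a subject with no blinks in a category and is excluded per cell, exactly as
footnoted in the reference tables (the n−1 convention was confirmed by
reproducing a printed "± 0.1" from its printed column, computed 0.095).
Per-tap group cells average each subject's count at that tap over the
subjects that reached it.

Group comparisons use the Wilcoxon rank-sum test, two-sided, on midranks.
For pooled sizes up to 20 — every cohort in the reference study — the null
distribution of the rank sum is computed exactly by a subset-sum
convolution over doubled midranks (doubling keeps tied midranks integral),
and the two-sided p is `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. This
convention reproduces all six published width-comparison p-values to four
decimals from the packaged per-subject values; R's `wilcox.test` differs
under ties (it refuses an exact null), which is why the null is authored
here and `wilcox.test` serves only as a tie-free cross-check in the tests.
Beyond the pooled size of 20 the normal approximation with tie and
continuity corrections takes over; the two branches agree within 0.02 at
n = 10 vs 10. The before/after-medication comparison is run as an unpaired
rank-sum — the same patients appear in both samples, but the unpaired test
is what the reference analysis names, so that choice is mirrored and noted
here. The Shapiro–Wilk screen runs per group on raw data and under the
x², 1/x, √x, ln x ladder, each transform only where its domain allows
(reciprocal and log need all-positive data, square root non-negative);
inapplicable transforms are reported as such, never silently skipped. No
multiple-testing correction is applied, matching the reference analysis.

One transcription note: the packaged healthy-control non-reflex width
column averages to 0.145 while the printed summary row shows 0.143 —
presumably rounding of unrounded underlying data. The packaged fixtures
carry the printed per-subject values verbatim, so the recomputed 0.145 is
reported as computed and the discrepancy is documented rather than patched.
The study's subject-level per-tap counts (and hence its count-comparison
p-values) are not recoverable from the published tables; only the width
comparisons are recomputable, and only those are reported.

## The synthetic generator

`sample_session()` draws 5–8 taps at an irregular rhythm slower than
2 taps/s (inter-tap intervals uniform on 0.6–2.5 s), gives each tap a
reflex blink with probability `p_reflex_per_tap` at a latency drawn from
(10, 180) ms — strictly interior to the classification window, so boundary
conventions can never flip a synthetic label — and adds spontaneous blinks
as a Poisson process thinned by a 0.05 s guard around every reflex window
and a 1 s dead time around any other blink apex, which guarantees pulses
never merge. Blink waveforms are raised cosines because their width at
half maximum equals the duration parameter exactly, making ground truth
unambiguous; durations are uniform on 0.05–0.45 s, the range spanned by
the published width tables, with reflex durations capped so that
neighbouring-tap pulses stay disjoint. Defaults chosen once as study
conditions: `p_reflex_per_tap = 0.9` (published iPD per-tap reflex rates
are ~0.94, healthy controls lower), `non_reflex_rate_hz = 0.5`
(published non-reflex counts of ~0.3–1.2 per ~1.5 s inter-tap interval),
glove/skin blue levels 220/90, 0.15 s contact, 25 Hz flicker of amplitude
2, Gaussian noise SD 1.

`render_session()` draws a deliberately schematic face: a flat skin patch,
elliptical eye apertures whose height follows the blink closure (the
camera-near eye larger, emulating the 45° angle), eyelid landmarks on the
aperture, and a glove rectangle whose colour blends with the same 2-frame
contact ramp as the direct signal synthesis, so the pixel route and the
signal route agree to within quantisation. The eyes are drawn large
relative to a real face so the aperture spans ~18 pixel rows at 64×64
frames; with fewer rows the staircase in the pixel count distorts recovered
widths by tens of milliseconds. What the renderer does **not** emulate:
photorealism, landmark-model error characteristics, head motion, occlusion
by the examiner's hand, or generative group differences (cohort contrasts
enter only through configuration). Passing recovery tests therefore
demonstrate the correctness of the signal-to-statistics chain, not
robustness to real-world face-tracking noise.

## Validation problem sizes

The shipped suite validates, among other properties: exact reproduction of
every targeted printed table cell from the packaged fixtures; recovery of
tap/blink counts, categories, apex times (≤ 1 frame) and widths (mean
absolute error ≤ 1 frame interval) on 50 rendered noiseless sessions at
64×64 px with the 10 Hz validation cutoff; agreement of prominence and
width with a brute-force all-samples oracle, and of the exact rank-sum
with full enumeration for all pooled sizes ≤ 12; a 2,000-replicate
type-I-error calibration at n = 9 vs 9 (nominal band 0.03–0.07); and
25 Hz flicker attenuation below 10⁻³ with apex positions untouched by
filtering. Landmark serialisation is exercised at 400 frames × 468 points
with a 10⁻⁹ round-trip tolerance.

## Known limitations

* The landmark provider is pluggable but no face-mesh model ships with the
  package; real-video performance is bounded by the external tracker.
* The blinking signal measures lid aperture by pixel count, so eyelash
  shadows, specular reflections or extreme gaze shifts can modulate it in
  ways the generator does not model.
* At the 0.75 Hz analysis cutoff, blink widths are systematically widened;
  width studies should use a higher per-channel cutoff (the validation
  suite uses 10 Hz) or interpret widths comparatively.
* The exact rank-sum is quadratic in pooled sample size times total rank
  mass; it is intended for the small-cohort regime (≤ 20) it defaults to.
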