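---
title: "Quantitative ciliary beat-pattern analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ciliary beat-pattern analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliokin)
```

## The measurement model

A respiratory cilium beats in a roughly planar cycle: a fast propulsive
*power stroke* from an extreme position `P1` to the opposite extreme `P2`,
an optional pause, a slower *recovery stroke* back to `P1`, and an optional
pause before the next cycle. `ciliokin` quantifies this from the minimal
annotation a human (or the package's own tracker) can produce on
frame-by-frame playback of a high-speed recording: three landmarks — the
base `P0` and the tip extremes `P1`, `P2` — and five time-points
`t1 ≤ t2 ≤ t3 ≤ t4 ≤ t5` bounding power stroke, mid-cycle pause, recovery
stroke and end-cycle pause.

Twelve parameters follow. Length is the longer base-to-tip distance;
the beating angle is the angle `P1–P0–P2` by the law of cosines; the global
frequency is the reciprocal cycle duration `1/(t5 − t1)`; the four phase
durations partition the cycle exactly, so `Dp + Dr + Ps + Pr = 1/Fg` holds
to arithmetic precision — this closure is asserted as an invariant
throughout the test suite. The tip's distance travelled per second is the
arc length `Lc·θ·Fg` and the area swept per second the sector area
`(θ/2)·Lc²·Fg`; both are also reported weighted by the patient's fraction
of beating ciliated edges. Two consequences are worth noting:

* the formulas only produce the published magnitudes when the angle is in
  radians, so angles are stored in radians throughout and converted to
  degrees only for display;
* the arc is counted once per cycle, exactly as the sector formulas read,
  not once per stroke. Counting both strokes would double the rates; we
  implement the formulas verbatim and document the convention rather than
  second-guess it. The identity `dist = 2·area/Lc` then holds whenever
  `Lc > 0` and is tested as a property.

Cilia that beat but never complete an identifiable cycle (the tip does not
return) are flagged `cycle_observed = FALSE` and contribute zero frequency,
durations and rates while keeping their geometry. This zero-by-convention
path matters clinically: severely dyskinetic patients can show residual
motion on every edge and still have a weighted distance of exactly zero.

Assumptions: the beat is planar and recorded in the focal plane; the base
is stationary over the annotated cycle; the cilium is straight enough that
the tip arc approximates the swept area (the bending of the shaft during
the recovery stroke is deliberately not modelled — capturing it would need
more landmarks per frame and a different parameterisation).

## Edge scoring and patient summaries

Twenty distinct epithelial edges per patient are each given a beating score
(1, 0.5 or 0 for a majority, about half, or a minority of cilia beating), a
qualitative pattern label (normal, virtually immotile, stiff, circular) and
a dyskinesia grade in [0, 3]. The beating fraction is the score sum over
the number of areas and is kept as a fraction in [0, 1]: the published
weighted-distance magnitudes are only consistent with a unit-interval
multiplier, not a percentage. Dyskinesia grades are accepted as any real
value in [0, 3] rather than integers only — patient-level means like 0.13
imply fractional bookkeeping upstream, and accepting reals loses nothing.
Patient summaries carry the mean and the sample (n − 1) standard deviation
of each kinematic parameter over the (nominally ten) cilia; the sample SD
is the conventional small-sample choice. Fewer than 20 edges or 10 cilia
warn rather than error, so partial recordings remain analysable.

## Gold standard and the diagnostic rule

The gold-standard partition is a pure function of three clinical inputs:
PCD requires > 90% ultrastructurally abnormal cilia *all sharing one
defect* with nasal NO output < 100 nl/min; non-PCD requires < 20% abnormal
cilia with NOn ≥ 100 nl/min; everything else — discordant TEM and NOn — is
inconclusive. Heterogeneous ultrastructural phenotypes fail the
shared-defect clause by definition.

The classifier (`cbp_classifier`) is an empirical ROC over a single
patient-level parameter, by default the mean weighted distance travelled
per second with *lower* values indicating disease. Candidate thresholds
are the midpoints between adjacent distinct pooled values, bracketed
outside the observed range; sensitivity counts positives strictly beyond
the threshold, so a value equal to a cutoff is conservative. The AUC is the
trapezoidal area and equals the tie-corrected Mann–Whitney statistic
divided by `n1·n2` — an identity the tests verify on random tied instances
and against an independent ROC implementation. Three named operating
points are extracted: the Youden-maximising *balanced* cutoff (first
maximiser along the sweep if tied), the 100%-sensitivity cutoff with
maximal specificity, and the 100%-specificity cutoff with maximal
sensitivity. The rule by which the original 24 μm balanced cutoff was
chosen is not derivable from patient-level data, so `predict` and the
pipeline accept externally established cutoffs verbatim; the Youden
maximiser is this package's own choice of balanced rule.

Three-zone classification uses strict inequalities: below the
100%-specificity cutoff supports PCD, above the 100%-sensitivity cutoff
excludes it, and boundary-equal values stay indeterminate — the
conservative reading for a diagnostic aid. With perfectly separated
training groups the two 100% cutoffs coincide and the fitted grey zone has
zero width; meaningful grey zones come from measurement-level data or from
externally supplied cutoffs.

ROC analysis on patient means and on individual cilium measurements are
both supported (the fitting functions take plain vectors); the bundled
reference cohort only carries patient-level means, so the package's
recomputable checks operate at that level and the measurement-level
statistics are covered by the AUC–U identity and the other property tests
instead.

## The synthetic test bed

The generator exists so that every pipeline stage is testable without
patient video, with known ground truth.

**Beat model.** The tip angle about a fixed base follows a plateau–ramp
cycle: dwell at the `P1` angle for the pause after recovery, linear sweep
through the beating angle over the power-stroke duration, dwell for the
pause after stroke, linear sweep back over the recovery duration. Constant
angular velocity is the simplest kinematics consistent with the five
time-point description, and the annotation scheme only uses endpoints and
dwells, so nothing downstream depends on the ramp shape. Phase durations
are specified as duty fractions of the period and close to `1/Fg` by
construction. Gaussian angular noise (default 0) models tip jitter. The
"circular" pattern — recorded clinically but without published kinematics —
is rendered as tip motion on a 2:1 ellipse about the base with no dwells;
this is a stated convention of the simulator, and the annotator correctly
reports no dwell-bounded cycle for it.

**Rendering.** Defaults mirror the reference acquisition: 355 frames/s,
1800 frames, 256 × 192 pixels of 0.13 μm — all overridable. Each frame
draws the base-to-tip segment sampled at tenth-pixel steps and splatted
bilinearly (an anti-aliased line; binary rasterisation leaves staircase
artefacts that bias sub-pixel tracking), blurs it with a Gaussian PSF
(default σ = 0.3 μm, a plausible high-NA width) via `EBImage::gblur`, and
adds Gaussian read-out noise at a chosen peak SNR. Values are clamped to
[0, 1]; stacks round-trip through 16-bit grayscale multi-page TIFF.

**Tracking.** Per frame, pixels above `threshold × max` (default 0.5) form
the foreground and the foreground pixel farthest from the base seeds the
tip estimate. Refinement exploits a property of blurred segments: along
the ridge, intensity falls to half the ridge level exactly at the segment
endpoint, so the outermost half-maximum crossing of the base-to-tip ray
profile locates the tip radius at sub-pixel precision, and an
intensity-weighted centroid across the ray (window ± 6 px, wider than the
PSF) fixes the cross-track offset. Three such iterations re-aim the ray.
A uniformly dark frame raises a tracking failure naming the frame.

**Automatic cycle annotation.** The tip's unwrapped angle about the base is
median-filtered (window 5), and a lagged slope (default 3 frames)
classifies each step as dwell or sweep against a threshold of 20% of the
98th-percentile step (robust to isolated spikes; an explicit `omega_eps`
overrides it). State runs shorter than `min_run` (default 5 frames, about
14 ms at 355 fps) are merged into their longer neighbour — tip jitter
comparable to the slow recovery step otherwise fragments the sweep. The
first dwell→sweep→dwell→sweep→dwell sequence bounds the reported cycle;
landmarks are taken as the mean tip position over the interior of the
dwell adjacent to each angular extreme (jitter averages out there), falling
back to the single extreme frame when a pause is too short to register.
Trajectories with no complete cycle return `cycle_observed = FALSE`, which
is a data state, not an error.

Quantisation limits are inherent: time-points are frame times, so the
recovered period is exact to one frame quantum, and at high beat
frequencies with large amplitudes the angular step per frame (e.g. ~12°
per frame at 12 Hz, 120° amplitude, 355 fps) bounds the achievable angle
accuracy. The package's accuracy checks therefore run at 2.5 Hz with a 90°
amplitude, where the tests show frequency recovered to the frame quantum,
angle within 2° and tip positions within half a pixel RMS in the
noise-free limit.

**Cohort generator.** Two built-in profiles bracket the clinical spectrum.
The non-PCD-like group draws beating fraction 0.95 ± 0.05, length
6 ± 0.5 μm, amplitude 1.2 ± 0.15 rad, frequency 9 ± 1.5 Hz, dyskinesia
0.3 ± 0.2 — a mean weighted distance near 60 μm. The PCD-like group draws
fraction 0.35 ± 0.10, amplitude 0.45 ± 0.10 rad, frequency 3 ± 0.8 Hz,
dyskinesia 2.5 ± 0.3, with 20% of cilia lacking an observable cycle — a
mean weighted distance near 3 μm. Clinical margins are drawn uniformly
inside the corresponding gold-standard regions. These centres sit inside
the observed group ranges of the reference cohort; the ± widths are chosen
so the groups remain separated at patient level without being degenerate.
Normal draws are truncated at physical bounds. Per-cilium annotations are
emitted analytically from the drawn beat model (no rendering), and a
single RNG stream keyed by one seed drives everything, so cohorts are
bit-reproducible.

What the simulator does *not* emulate: metachronal coordination between
cilia, mucus load, shaft curvature, out-of-plane motion, photobleaching or
camera-specific noise. Passing round-trip tests therefore demonstrates the
internal consistency of the pipeline — annotation faithfully inverts the
generative model under realistic geometry and noise — not that the tracker
would segment real bright-field video, where the annotation is expected to
remain manual.

## Numerical choices

* The law-of-cosines argument is clamped to [−1, 1]; collinear landmarks
  give exactly 0 or π instead of NaN.
* A tip landmark coinciding with the base is a degenerate geometry error in
  `beating_angle` itself, but `compute_cycle_parameters` substitutes angle
  0 for such cilia — the flagged-immotile convention.
* ROC thresholds are value midpoints, so results do not depend on which
  side of an observed value a cutoff nominally sits; ties in the Youden
  sweep resolve to the first maximiser.
* Reported TIFF stacks are 16-bit, so a write/read round trip is exact to
  1/65535.
* File formats are header-mandatory CSV/TSV with `.` decimals; coordinates
  are stored in pixel units and frame indices (0-based) exactly as
  annotated on video, and converted once on read — micrometres and seconds
  everywhere in memory.

## Problem sizes

The test suite and acceptance script run the full rendering round trip on
one 355-frame full-field stack plus several smaller stacks (≈ 100–160 px
fields, 5–160 frames), and the cohort checks use 6–40 synthetic patients
(20 + 20 for the ROC separation check). These sizes keep the whole suite
in the tens of seconds on a single core while still exercising every
branch; all generators scale to arbitrary durations and cohort sizes.

## Known limitations

* The beating angle is an amplitude proxy; shaft bending, especially
  during the recovery stroke, is not measured.
* Patient-level and measurement-level ROC can differ; only patient-level
  numbers are recomputable from the bundled cohort.
* The qualitative pattern labels and dyskinesia grades are inputs — the
  package aggregates them but never infers them from video.
* The automatic annotator assumes a dwell-bounded planar cycle; rotational
  ("circular") beating is detected as absence of such a cycle rather than
  parameterised.
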