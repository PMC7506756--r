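---
title: "Measuring visual fatigue from infrared pupillometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring visual fatigue from infrared pupillometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilfatigue)
```

# The measurement problem

Prolonged display viewing fatigues the visual system. Subjective
questionnaires are unreliable and contact biosignals (skin conductance,
photoplethysmography) are confounded by temperature, humidity and movement.
An eye-image-based measure avoids both problems: a head-mounted near-infrared
camera films the eye at 30 fps while the subject watches a display. Under
off-axis IR illumination the pupil is the darkest region of the image
(dark-pupil imaging), so its area can be tracked frame by frame, and three
features of the resulting size signal index fatigue:

* **pupil accommodation speed** — the iris muscles tire, so the rate at which
  pupil size changes between contraction/expansion reversals falls;
* **blink frequency** — tired, dry eyes blink more;
* **eye-closed duration** — tired eyes stay closed longer.

This vignette explains each stage's model and assumptions, the tunable
parameters, the synthetic data the package tests itself against, and the
design decisions taken where more than one reading was defensible.

# Pupil detection

## Mask sources

The pipeline consumes per-frame *binary pupil-candidate masks* and is
agnostic about where they come from. Two backends ship:

* `threshold`: pixels darker than `intensity_thr` (default 80 of 255) are
  candidates, then a morphological opening removes speckle and a closing
  fills holes punched by corneal glints (disc radius `morph_radius`, default
  2 px; order fixed as opening-then-closing). This classical dark-pupil
  baseline is deterministic and fully testable.
* `external_masks`: pass-through for masks computed elsewhere, e.g. by a
  semantic-segmentation CNN. Mask files on disk are 0/255 PNG, normalized to
  0/1 on read.

Mask quality is scored by pixel IoU, with mean IoU over a frame set. Two
empty masks score IoU 1 — both agree there is no pupil, the correct verdict
on a closed-eye frame. This convention matters because blink frames are a
routine part of every recording.

## Candidate post-processing

Segmentation occasionally marks regions outside the pupil (eyelashes, eyelid
shadow). Post-processing removes them using two facts: pupils are
near-circular, and pupil size varies little across subjects at a fixed
camera geometry.

Connected components of the mask become candidates. For each, the package
records the filled component area *CA* (interior holes are filled first —
a glint hole belongs to the pupil; only the outer boundary delimits it), the
axis-aligned bounding box *W* × *H*, and the aspect ratio
min(*W*, *H*)/max(*W*, *H*) ∈ (0, 1]. A candidate survives iff

* *CA* > `ca_thr` (default 300 px), and
* aspect > `as_thr` (default 0.4), and
* *CA* < `ca_max` when that optional upper bound is enabled (off by
  default).

Both comparisons are strict. The aspect ratio is deliberately symmetrized:
a raw *W*/*H* test treats a tall elongation differently from a wide one,
while min/max rejects both equally, and a near-circular pupil (ratio ≈ 1)
comfortably survives the 0.4 cutoff. One published description of this
filter reads as *removing* candidates whose ratio exceeds the threshold;
that direction would delete every circular pupil, so the keep-if-above
reading is adopted and flagged here.

The largest survivor is the pupil (ties go to frame-scan order); no survivor
means the frame's size is 0. A direct least-squares conic fit constrained to
ellipses is applied to the survivor's outer boundary, and the frame's pupil
size is the fitted ellipse area πab — smoother against pixelation than the
raw pixel count. Two numerical details:

* contour points are centered and isotropically scaled before the
  eigen-solved fit, for conditioning;
* the fitted semi-axes are inflated by 0.5 px before computing the area,
  because boundary *pixel centers* lie on average half a pixel inside the
  continuous region boundary. Without the correction a radius-20 disk is
  under-measured by ≈ 4.5%; with it, rasterized circles and ellipses are
  recovered well within the 5% the test suite demands.

Contours with fewer than 5 points cannot determine a conic; such frames
become no-pupil frames with a warning.

# Fatigue features

## Inflection points and accommodation speed

Pupil convergence/divergence takes seconds, so differencing adjacent 33 ms
frames measures noise, not accommodation. Instead the signal's reversal
points are found and the speed is averaged between them. With accepted
inflection points (*F₁*, *S₁*) … (*F_{N+1}*, *S_{N+1}*):

P = (1/N) Σₙ |Sₙ₊₁ − Sₙ| / |Fₙ₊₁ − Fₙ|, reported in px/frame with a
px/s convenience (`P * fps`).

Candidates are the sample-level extrema of the (optionally median-smoothed)
signal, computed independently within each maximal non-zero segment; zero
runs are excised first because a 0 sample is sensor dropout (closed eye),
not a pupil size, and no accommodation interval should span a blink.
Segment endpoints are included as candidates (an accommodation swing cut by
a blink still carries slope information); segments shorter than 3 frames —
a momentary opening between two blink components — contribute a single
median-valued candidate, since two raw samples 33 ms apart cannot witness a
swing but their noise difference would otherwise masquerade as one.

Selection is a greedy left-to-right scan. The first candidate anchors the
walk; a candidate is accepted when (1) its size difference from the
previously accepted point alternates in sign against the previous accepted
difference and (2) the absolute difference exceeds `delta_thr`. Among
consecutive candidates continuing in the same direction the most extreme
replaces the previous acceptance, so each swing terminates at its true
extremum rather than at the first large-enough wiggle. Two postconditions
hold by construction and are asserted in tests: accepted difference signs
strictly alternate, and every accepted step exceeds the threshold.

Parameters:

* `delta_thr` (px). No canonical value exists for the "insignificant
  wiggle" threshold; the default `"auto"` is 5% of the interquartile range
  of the non-zero areas, which scales with both pupil size and oscillation
  amplitude so the same setting works across traces. Override with a fixed
  pixel value for cross-recording comparability.
* `smoothing_window` (frames, odd; default 1 = off). A moving median
  (`runmed`) applied per segment before extrema detection. For noisy traces
  we recommend 9 frames (0.3 s at 30 fps): it suppresses frame-level noise
  while leaving multi-second accommodation swings intact. The window is
  clamped to short segments and the `constant` end-rule is used so segment
  ends cannot contribute raw-noise extrema.

Degenerate conventions: fewer than 2 accepted points → P = 0 (no completed
swing observed); duplicate frame numbers are an error.

## Blink frequency and eye-closed duration

Both depend only on the zero/non-zero pattern. A blink is one *maximal run*
of zero frames; blink frequency is runs per second of recording. Leading and
trailing zero runs count — a truncated blink is indistinguishable from a
complete one. Eye-closed duration is the total zero-frame count, reported in
frames, in seconds (frames/fps), and as closed seconds per second of
recording (a dimensionless occupancy in [0, 1]). An all-zero series is one
blink run covering the recording, with occupancy 1 and P = 0.

As a worked check: a 10-s, 30-fps series whose zero frames form runs of
6, 1, 5, 8, 6 blinks 5 times (0.5 blinks/s) and is closed 26 frames = 0.87 s,
i.e. 0.087 s per second of recording.

# Condition comparison

Per-segment features are compared between a reference viewing condition and
optically modified ones. The underlying test is deliberately pluggable since
the appropriate choice depends on the design: the default is Welch's
two-sample t (independent sessions, unequal variances plausible), with
Student's t, Mann-Whitney, paired t and Wilcoxon signed-rank as
alternatives — paired variants for within-subject designs. All tests are
two-sided; the fatigue hypotheses are directional, but sidedness is left to
the analyst rather than assumed. Identical zero-variance samples return
p = 1 by convention. Significance stars follow p < 0.01 (\*\*\*),
p < 0.05 (\*\*), p < 0.1 (\*), strict at each boundary; the 0.1 level is
included because fatigue effects in modest samples are often suggestive
rather than decisive. No multiple-testing correction is applied by default
(features are reported per comparison); apply `p.adjust` externally if your
design needs family-wise control. `feature_table()` prints feature ×
condition means at 4 decimals with stars attached.

# Synthetic data: what it emulates, and what it does not

Recordings of this kind (20 subjects, 30 fps, 640 × 480, ~16 min) are not
generally shareable, so the package ships a two-level generator whose
defaults were fixed once, from the recording conditions just described, and
are treated as study conditions rather than tuning knobs:

* **Signal level** (`generate_signal`): area(t) = `base_area` (1200 px ≈
  a 20 px-radius pupil) + `osc_amplitude` (300 px) · sin(2πt /
  `osc_period_s` (4 s)) + N(0, `noise_sigma`²), clipped at 0; blink count
  Poisson at `blink_rate` (0.5/s, the rate of the worked example above) with
  uniform durations of `blink_duration_frames` (1–8, the worked example's
  run lengths). Blink runs are placed without overlap (real blinks do not
  overlap; merging would bias the realized run count below the nominal
  rate), so the zero-run count is exactly Poisson-distributed.
* **Image level** (`render_frames`): each open frame draws a filled pupil
  ellipse of the requested area (eccentricity option for non-circular
  pupils) at a jittered center, inside an iris disc on a skin background,
  with bright corneal-glint speckles; blink frames are uniform eyelid at
  skin intensity with an empty truth mask. Default gray levels 30/120/200
  (pupil/iris/skin) respect dark-pupil ordering.

Ground truth carries the clean signal, blink flags, and `true_P`: the
inflection-speed summation applied to the interior extrema of the clean,
*blink-free* signal. Blinks are measurement dropouts — the oscillation
continues beneath them — so defining the speed oracle on the blink-zeroed
signal would create zero-slope pairs whenever a blink swallows an extremum
and corrupt the target.

Everything is deterministic per seed: one RNG stream per spec, saved and
restored around generation, so replicates never perturb the caller's RNG.

**What passing tests do and do not show.** The generator reproduces the
*structure* the pipeline assumes — slow oscillation, dropout blinks, glint
holes, near-elliptical dark pupils — but not eyelid occlusion ramps, gaze-
dependent pupil foreshortening, hippus, illumination drift, or segmentation
failure modes of real CNNs. Recovery results on synthetic data validate the
post-processing and feature algebra, not field accuracy on real eyes;
published mean-IoU figures for CNN segmentation of real recordings are not
reproducible without those recordings and are out of scope here.

# Problem sizes and verification

The test suite and the acceptance script verify, among others (sizes chosen
to exercise each stage fully):

* rasterized circles/ellipses recovered by the ellipse fit within 5%
  (radius-20 circle, 25 × 15 ellipse);
* threshold-candidates straddling the filter boundaries (areas 299/301,
  aspects 0.39/0.41) filtered exactly as a brute-force predicate scan;
* a 600-frame, 320 × 240 noiseless render recovered end-to-end with
  Pearson r > 0.99, per-frame areas within 5%, blink count exact;
* on noisy signals (σ = 5% of oscillation amplitude, 600 frames,
  median window 9), blink frequency exact and P within 10% of `true_P`;
* the comparison stage's empirical type-I error at p < 0.05 within
  0.05 ± 0.02 over 1000 null replicates;
* byte-identical artifacts across repeated seeded runs.

# Known limitations

* BMP input is not supported (PNG/TIFF only); convert beforehand.
* The threshold backend assumes dark-pupil contrast; bright-pupil (on-axis
  IR) recordings need external masks.
* W/H uses the axis-aligned bounding box, the simpler of the two plausible
  readings; a rotated (min-area) box would differ for oblique elongations.
* Accommodation speed is reported in px/frame (with px/s convenience); no
  millimeter calibration is attempted.
* Segments are analyzed as given; the package does not decide how a long
  recording should be cut into comparison segments.
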