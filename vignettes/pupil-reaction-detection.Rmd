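---
title: "Detecting pupil reactions from width signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pupil reactions from width signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilkinetics)
```

## The problem

During cataract surgery the pupil can contract (miosis) or dilate abruptly,
for instance when fluid is irrigated into the eye. These reactions matter
clinically — intraoperative miosis complicates lens centration, and the
pattern of pupil size variation is a candidate risk factor for
post-operative complications — but finding them by eye in hours of video is
impractical. `pupilkinetics` detects them automatically from per-frame
pupil and iris segmentations, which an upstream instance-segmentation model
(outside this package's scope) produces from the video frames.

## From segmentations to width signals

Each frame record carries a pupil and an iris region (tight bounding box,
optionally a binary mask from which the box is derived). A frame is usable
only when

* both classes were detected, exactly once each — frames with several
  candidate regions per class are rejected outright rather than resolved,
  because any resolution rule (e.g. "keep the larger") would silently hide
  upstream segmentation failures; and
* the pupil box lies fully inside the iris box, a cheap anatomical sanity
  check at box level.

The measurement is the **horizontal** extent of each box: the eye moves
vertically far more than horizontally under the microscope, so widths are
the stabler quantity, and the iris box width is taken as the limbus width.
Unusable frames get the widths of the most recent usable frame (pupil and
limbus jointly, from the same donor frame, so their difference stays
consistent); a leading run of unusable frames takes the first usable
measurement. The result is one pupil and one limbus width per frame,
aligned with the video timeline.

## Smoothing

Segmentation jitter makes the raw signals oscillate frame to frame, while a
pupil reaction unfolds over about a second. A Butterworth low-pass filter
with cutoff `f` between 0.01 and 0.2 Hz separates the two; it is applied
forward and then backward over the signal, so the net phase shift is zero
and detected extrema keep their true temporal position. The effective
amplitude response is the squared Butterworth magnitude.

Numerical choices that matter here:

* **Realization.** The filter runs as a cascade of second-order sections
  designed analytically via the bilinear transform. At a 0.1 Hz cutoff
  against a 12.5 Hz Nyquist the poles sit within 0.008 of the unit circle;
  a single direct transfer-function recursion at that conditioning carries
  a roundoff floor around 1e-8 relative, which the cascade lowers to
  ~1e-12. Linearity, unit DC gain and time-reversal symmetry hold to the
  tolerances the test suite asserts.
* **Edges.** Each pass starts from the steady state of a constant input
  equal to its first sample, after odd-extension padding. The padding
  length is sized from the slowest pole so the start-up transient decays
  below 1e-13 inside the padding (floored at 3× the order, capped at the
  signal length minus one). A short fixed padding is not enough at these
  cutoffs: the transient persists for thousands of samples and would
  otherwise leak several seconds of edge artifact into the signal.
* **Order.** The order is not pinned by the method — results should not
  depend on it — so it is a parameter with default 5, a common choice with
  a reasonably sharp knee. Note that the zero-phase step response of this
  filter over- and under-shoots a level change by roughly 15%, which
  slightly inflates measured segment sizes; this is inherent to Butterworth
  smoothing, not an artifact.

## Detection

The analyzed signal is either the smoothed pupil width or the smoothed
limbus-minus-pupil width ("difference" mode, which exploits the limbus
staying constant while the pupil reacts). Every span between two
neighboring local extrema of the analyzed signal is a candidate reaction;
its size is the difference of the signal values at the bounding extrema. A
candidate is kept when its absolute size reaches `Delta · DM`, where `DM`
is the median limbus width minus the median pupil width over the whole
video — a per-video size reference robust to noise and camera zoom.

Decisions taken where the method leaves room:

* `DM` uses the interpolated but **unfiltered** signals; medians are
  already noise-robust, and this keeps the reference independent of the
  cutoff under study.
* The first and last frames count as boundary extrema, so the leading and
  trailing monotone runs can be candidates.
* Plateaus (rare in a real-valued filtered signal) collapse to their first
  frame, a deterministic tie-break.
* In difference mode the threshold still uses the same `DM`, so a given
  `Delta` means the same physical size in both modes; the sign is inverted
  before labelling a segment constriction or dilation, since the
  difference signal rises when the pupil shrinks.
* Adjacent same-direction candidates are **not** merged; nothing in the
  extremum definition produces two adjacent candidates of the same
  direction except through an intervening extremum, which is evidence of a
  real reversal.
* Each reaction also carries the pupil/limbus ratio change between its
  endpoints, a zoom-invariant size on the smoothed signals: −0.12 reads as
  a 12-percentage-point constriction.

## Evaluation

Predictions are matched to interval annotations labelled weak / medium /
strong and obvious / unclear. An annotation counts as detected when a
prediction covers at least `containment_fraction` of it (default 1,
i.e. full containment — the strict reading; the fraction is configurable
because partial-overlap matching is a legitimate alternative). With `tp`
detected annotations, `fn` missed ones, `Pc` predictions detecting at
least one annotation and `fp` predictions detecting none:

* Recall `= tp / (tp + fn)`,
* Precision `= Pc / (Pc + fp)`,
* GTCR `= Pc / tp` (Ground Truth Coverage Rate — how many correct
  predictions stand behind the detected annotations; one long prediction
  blanketing three annotations scores 1/3),
* H = harmonic mean of the three (0 if any component is 0, the
  harmonic-mean limit, which also avoids division by zero).

The precision numerator deserves a note: the printed formula in the source
method is `tp / (tp + fp)`, but its own worked example — precision 33%
with three detected annotations and two wrong predictions out of three —
is only consistent with correct-predictions over all predictions. The
package implements the operational definition `Pc / (Pc + fp)`.

Before counting, an adaptive IoU filter can drop predictions whose
temporal IoU with every annotation is at most
`IoU_tr = min(GTL, PL) / max(GTL, PL)` (average annotated vs. average
predicted duration in seconds). The threshold is computed once from the
current sets — no fixed-point iteration — and the filter is off by default
only for the schematic fixtures of `fig7_fixture()`, which are defined
without it.

`run_sweep()` grids over `f × Delta × mode`, pooling the counts
(`tp`, `fn`, `fp`, `Pc`) across videos before computing metrics — the
simplest pooling consistent with single-number dataset results — and
selects the best H among configurations whose average prediction length PL
stays under a cap (default 60 s: a prediction much longer than a
one-second reaction is useless for review, however well it scores).

## The synthetic generator

`simulate_video()` emulates the statistics of an annotated 25 fps cataract
video collection: reaction durations normal with mean 1 s, sd 0.67 s,
floored at 2 frames (flooring rather than rejection-resampling — rejection
would inflate the sample mean by ~0.11 s, breaking the moment match);
intensity mix 72.6% weak, 14.8% medium, 12.6% strong; unclear-annotation
rates 50% / 0% / 5.9% by intensity. The pupil trace is a baseline plus,
per reaction, a logistic ramp over the sampled duration to a displaced
level and a later logistic return toward baseline midway before the next
reaction — mimicking the pupil's prevailing state between irrigation
phases. The limbus is constant up to the shared Gaussian noise, and a
uniform fraction of frames is dropped to exercise interpolation.

Defaults, chosen once as plausible for 540×720 surgery video: 240 s
duration, 8 reactions per video, limbus 400 px and pupil 220 px baselines
(so DM ≈ 180 px), noise sd 3 px, 5% dropout. The intensity size ranges —
weak (0.05, 0.10), medium (0.10, 0.20), strong (0.20, 0.40) of DM — are
declared simulator conventions: the source annotations never quantify the
intensity boundaries.

What the generator does **not** model: camera zoom drift, instruments
occluding the pupil, the eye leaving the illuminated area, correlated
segmentation failures, and asymmetric or partial reactions. Tests passing
on these simulations therefore demonstrate the pipeline's correctness and
its behavior under idealized noise — not the detection performance
attainable on real recordings, where evaluation against surgical
annotations remains necessary.

`render_eye_frames()` closes the loop for the I/O path: it rasterizes each
simulated frame as two concentric filled ellipses with the prescribed
widths, boxes them, and writes ordinary segmentation records; reading,
validating, measuring and interpolating those recovers the generating
trace within 2 px. The test suite runs this round trip on five 30-second
videos at a reduced 270×360 raster (limbus 180 px), and the detection
property checks use fifty 240-second signal-level simulations — problem
sizes picked to exercise every path while keeping the suite quick.

## Known limitations

* Width-only measurement ignores vertical pupil geometry; strongly
  elliptical distortions (eye rotation) alias into apparent size changes.
* The detector is offline by design: zero-phase filtering needs the whole
  signal, so it cannot run live during surgery.
* Intensity categorization of detections (weak/medium/strong) is not
  automated; detections carry sizes, the labels exist only on annotations.
* With `Delta = 0` every inter-extremum span is emitted, including
  zero-size spans of a perfectly flat signal — the grid's lower end is a
  diagnostic setting, not an operating point.
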