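---
title: "Simulating a closed-loop all-optical ventricular tachycardia platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a closed-loop all-optical ventricular tachycardia platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtloop)
```

## What is being simulated

A closed-loop optical-mapping platform images a voltage-sensitive-dye
(VSD) stained, channelrhodopsin-expressing heart at hundreds of frames
per second and, whenever a depolarization wave reaches a detection ROI
at the heart base, projects a blue-light spot onto the apex after a
fixed delay. The re-injected stimulus launches the next wave, and the
system settles into a self-sustained rhythm — an optically imposed
re-entrant ventricular tachycardia. `vtloop` reproduces the *software*
of such a platform faithfully (two asynchronous loops, single-slot
frame hand-off, shift-register detector, three-phase protocol) while
replacing camera, heart and projector with a deterministic simulation,
so that every timing property of the control loop becomes testable.

## The virtual heart

The tissue model is an activation-time (eikonal-style) description
rather than a reaction–diffusion PDE. This was a deliberate choice:
the closed-loop logic only consumes per-frame ROI means, so what must
be right are activation *times*, wave *speed*, signal *polarity* and
*amplitude* — all of which the eikonal model delivers analytically,
which in turn makes tests exact and runs deterministic and fast.

* A stimulus at time $t$ activates every non-refractory pixel under its
  mask and schedules an arrival at each remaining pixel at
  $t + d/cv$, with $d$ the Euclidean distance (mm, between pixel
  centers) to the nearest activated source and $cv$ the conduction
  velocity. An arrival at a still-refractory pixel is discarded rather
  than re-diffracted around the refractory region — adequate for the
  apex-to-base geometry used here, and noted as a simplification for
  complex re-entry geometries.
* Each activation plays a piecewise-linear action potential: linear
  upstroke over `upstroke_ms`, plateau of `apd_ms`, linear
  repolarization over `repol_ms`; re-activation is blocked for
  `refractory_ms`.
* Fluorescence per pixel is
  $F = f_0\,(1 - s\,v(t - t_{\mathrm{act}})) + \mathcal N(0, \sigma f_0)$,
  rounded half-away-from-zero and clipped to 16 bits. The dye signal is
  negative-going: depolarization *darkens* the pixel by $s f_0$ counts.

Default parameters (all configurable, murine scale): $cv = 0.5$ mm/ms,
upstroke 2 ms, plateau 40 ms, repolarization 20 ms, refractory 70 ms,
$f_0 = 10000$ counts, sensitivity $s = 4\%$, per-pixel noise
$\sigma = 0.4\%$ of $f_0$. With the default $0.1 \times 0.3$ mm ROI
(four pixels at the 10/128 mm pixel pitch) the ROI-mean shot noise is
$\sigma/\sqrt4 \cdot \sqrt2 \approx 0.28\%$ between two frames — the
upper edge of what the real platform tolerates at a 1% threshold.
Frames are point samples at frame time; the exposure only sets the
frame interval, because the detector consumes per-frame ROI means, not
exposure integrals.

Coordinates: the mm origin sits at the outer corner of the top-left
pixel, $x$ rightwards along columns, $y$ downwards along rows; pixel
indices are 1-based in R matrices while frame indices and timestamps
start at 0. Rectangular masks are half-open, circular masks use strict
interior membership (so a zero-diameter spot is empty and an error).

## The event engine

Time is integer microseconds on a deterministic discrete-event clock
(sub-millisecond protocol steps such as the 5 ms pulse need better than
ms resolution; integers keep the arithmetic exact). Wall-clock
threading is deliberately absent: simulated time is authoritative, which
is what makes whole-session bit-reproducibility possible.

The camera publishes a frame every `exposure_us` into a single-slot
latest-frame buffer; the imaging loop (IL) reads the newest frame as
soon as it is free (`il_cost_us` per frame), and a frame overwritten
unread is counted *lost*. This single-slot semantics is the simplest
mechanism consistent with a poll-the-newest-frame acquisition API, and
it reproduces the qualitative exposure-versus-loss behaviour of the
real platform: with IL cost below the exposure nothing is ever lost;
at 1.5 ms cost and 1 ms exposure exactly one frame in three is
overwritten.

The real-time loop (RTL) classifies every acquired frame into exactly
one of: `analyzed`, `protocol-window` (detector disarmed during a
stimulation protocol — an intentional skip), `rtl-busy` (analysis of
the previous frame still running), or `rtl-off` (free-run mode). The
conservation identities *produced = acquired + lost* and
*acquired = analyzed + skipped(...)* hold exactly and are asserted in
the tests; the two error-rate metrics are

* IL error rate = lost / produced,
* RTL error rate = rtl-busy / (acquired − protocol-window).

Protocol-window skips are excluded from both numerator and denominator
of the RTL metric so that it measures analysis *capacity* rather than
protocol design — a declared choice, since the original stress-test
description does not specify how stimulation windows were treated.

### Detector semantics

The shift-register buffer holds up to `buffer_len` past ROI means
(default 10 — two upstrokes' worth at 2 ms frames, long enough to span
a murine upstroke yet short enough to keep the comparison local). The
relative-variation vector is $(b_i - m)/b_i$; the comparison is
*strictly greater than* the threshold, so boundary equality does not
trigger. The triggering mean is not appended (the buffer is reset at
protocol end anyway). Only positive variation — a fluorescence drop —
triggers, matching the dye polarity; repolarization never fires the
detector. After a detection the engine disarms the detector, applies
the light pulse to the tissue once at pulse *onset* (channelrhodopsin
latency is ignored; the pulse width shapes only the log and the re-arm
time), and re-arms with a cleared buffer at
`pre + pulse + post` after the event.

## The period closed form

For loop geometry with stimulus mask $M$, detection ROI $R$ and
pre-activation delay $T_{pre}$, `predict_period()` returns the interval

$$T_{pre} + \frac{d_{\min,\max}(M,R)}{cv} +
  \frac{Th}{s}\,t_{\mathrm{up}} + [\,\epsilon_{lo}, \epsilon_{hi}\,],$$

where $d_{\min}, d_{\max}$ are the nearest/farthest ROI-pixel distances
to the mask, $\frac{Th}{s} t_{\mathrm{up}}$ is the part of the upstroke
needed for the ROI mean to cross the threshold, and the slack spans up
to **two** frame intervals: one of sampling quantization, and one
because the buffer is empty after each protocol reset, so the first
analyzed frame merely seeds it and comparison resumes one frame later.
The protocol window itself plus that seeding frame is a floor on the
cycle length (binding when the wave would arrive before re-arming).
Measured mean periods sit inside this interval across a grid of
pre-delays (50–400 ms) and conduction velocities (0.3–0.8 mm/ms) in the
acceptance tests; that grid uses a faster-recovering tissue variant
(plateau 20 ms, repolarization 10 ms, refractory 35 ms), because the
shortest grid period (~60 ms) is below the default 70 ms refractory
period, which would extinguish the re-entry — physiologically the same
statement as "a tachycardia cannot cycle faster than the tissue can
recover".

## What the synthetic data do and do not show

The generator emulates: the geometry and timing of apex-to-base
propagation, the negative-going VSD signal with ~4% sensitivity,
ROI-level shot noise up to the 0.2% ΔF/F ceiling, ChR2-like activation
under a patterned spot, and loss under load in a free-running
acquisition. It does **not** emulate ionic dynamics, APD restitution,
wavefront curvature, motion artifacts, photobleaching, illumination
inhomogeneity, or light-intensity-dependent excitation (LED current
fields in the configuration are logged but physically inert). Passing
tests therefore validate the *control software's* timing, detection and
accounting logic — not electrophysiological realism, and not the
hardware-dependent absolute error rates of any particular camera link,
which is why the stress harness reports its own configurable-load curves
rather than reproducing published hardware numbers.

One statistical property carries over to real use: at the default noise
ceiling the 1% threshold is about $3.5\sigma$ of the frame-to-frame ROI
variation, so over long armed periods occasional noise-driven triggers
occur, exactly as a real detector at that margin would experience. The
closed-loop rhythm is robust to them (a false trigger only phase-shifts
one cycle), but quiescent-recording analyses in the tests use
noise-free tissue where the intent is to verify plumbing rather than
false-alarm statistics.

## Numerical choices and degenerate inputs

* Fluorescence rounding: half-away-from-zero, then clip to [0, 65535].
* Refractoriness is a strict inequality (an interval exactly equal to
  the refractory period does not re-excite).
* Arrival times are continuous (double precision); frame and protocol
  times are integer microseconds.
* Ties in the activation-map steepest-drop search resolve to the
  earliest frame pair; pixels whose amplitude range stays below half
  the full depolarization drop are reported `NA`. The steepest-drop
  midpoint sits inside the upstroke, a bias below 1.5 frame intervals —
  irrelevant to conduction-velocity regression, which uses differences.
* Population (not sample) SD for cycle-length statistics, fixed for
  determinism of the CV at small event counts.
* Empty masks, empty ROIs, zero buffers, duplicate timestamps and
  wrong-shape TIFFs are errors, not warnings.
* Timestamp filenames are zero-padded to 12 digits so lexicographic
  equals numeric order for sessions up to ~11.5 days.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely from generated
data: the long stability check simulates 3 minutes at 2 ms exposure
(90 000 frames, detection-ROI rendering only), the stress checks 90 s
at 1 ms, oracle-equivalence replays ten 1.3 s full-frame sessions
through saved TIFF stacks, and the acceptance script summarises a 60 s
closed-loop run plus short wave recordings. These sizes were chosen as
the smallest that exercise hundreds of re-entry cycles and tens of
thousands of hand-off decisions.

## Known limitations

* The eikonal tissue cannot bend waves around refractory obstacles, so
  figure-of-eight re-entry or fibrillation-like dynamics are out of
  scope; the loop studied here is the imposed apex–base circuit.
* One static stimulation mask per protocol (no DMD pattern sequences).
* Slot depth is fixed at one frame, matching the latest-frame
  acquisition contract; a deeper hardware queue would lower loss at the
  same cost and would need a different hand-off model.
* The wall-clock/threaded mode of a real implementation is out of
  scope; all guarantees are about the simulated clock.
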