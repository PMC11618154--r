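---
title: "Methods: gaze-contingent calibration, validation metrics and the synthetic participant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-contingent calibration, validation metrics and the synthetic participant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecal)
```

## The problem

Calibrating a screen-based eye tracker means estimating, per eye, a mapping
from the tracker's raw gaze estimate to true screen position, using samples
collected while the participant fixates known target locations; validation
then quantifies the result at further known locations. For participants who
cannot follow instructions, target presentation must itself be driven by
gaze: a target is shown, the software watches where the participant looks,
and data collection is triggered only once gaze has dwelt near the target
long enough. `gazecal` implements this entire loop — state machine,
automation contract, automated procedures, quality metrics, calibration
fit — together with a synthetic participant that replaces the hardware,
so every behavioral guarantee of the procedure can be exercised in code.

## Geometry and angular computations

All screen positions are normalized coordinates in $[0,1]^2$ (origin
top-left, y downward); off-screen gaze is representable and tested with
`on_screen()`. For angular quantities the screen is modeled as a planar
rectangle with the eye, by default, on the screen-center normal at the
configured viewing distance (600 mm default) — the standard desktop-tracker
arrangement. When samples carry 3D eye origins those are used instead; when
they do not (minimal replayed logs), the nominal distance keeps every
metric computable. The angular offset between two screen points is the
exact angle subtended at the eye between the 3D vectors to their physical
locations, computed with `atan2` of the cross- and dot-products for
numerical stability near zero. For separations under 2° on the
screen-center normal this agrees with the small-angle approximation to
within 1% (a property verified in the test suite).

## Data-quality metrics

Per validation point, metrics are computed for the left eye, the right eye,
and the *per-sample binocular-average signal* (the mean of the valid eyes'
positions, sample by sample):

- **Accuracy**: mean angular offset between samples and the target. The
  mean (not median) per-sample offset is used, matching common practice;
  a median variant is exposed via configuration. Published-style
  multi-session medians apply *across sessions*, not within points.
- **RMS-S2S**: root mean square of angular distances between consecutive
  valid samples. Pairs bridging an invalid sample are excluded rather than
  interpolated, so blinks do not manufacture artificial jumps.
- **STD**: the root of the summed per-axis population variances of the
  samples' angular positions (azimuth/elevation as seen from the eye) —
  the RMS deviation from the mean position. For i.i.d. isotropic Gaussian
  noise, RMS-S2S/STD → √2; the suite checks this at n = 10,000 within 5%.
- **Data loss**: `100 · (1 − n_valid / n_expected)` with
  `n_expected = round(duration · rate)`, clamped to [0, 100]. When the
  nominal rate is unknown the received-sample count is the denominator and
  the result is flagged — the two conventions differ whenever samples are
  dropped entirely rather than flagged invalid.

Aggregates over validation points are unweighted means across the points
for which data is available, regardless of per-point sample counts.
The "average" column of multi-session summaries is taken to be the
binocular-average *signal*, not the mean of the two eyes' metric values:
published per-participant rows where the average-eye accuracy exceeds both
single-eye accuracies rule out the simple mean of metrics.

## The calibration stand-in

Commercial trackers compute calibrations internally with undisclosed
algorithms; `fit_calibration()` is a deliberately simple, documented
stand-in. Per eye, a least-squares mapping is fitted from raw samples to
target positions, with the family chosen by the number of usable points
(≥ 10 valid samples by default): one point gives a pure translation, two
distinct points a similarity transform, three or more non-collinear points
a full affine transform. This laddering matters because the automated NHP
procedure calibrates from as few as two locations and the adult demo's
first stage from one. Degenerate layouts (coincident or collinear targets)
fall back to the next-lower family with a note. Plain least squares is the
default; an optional trimmed refit (drop the worst 20% of residuals once)
is available behind configuration.

Real trackers can also *reject* a calibration. The stand-in's proxy is a
residual sanity bound: if the fit's residual RMS (normalized screen units)
exceeds `max_residual_rms`, the calibration fails, the procedure discards
all collected data and recollects. The default bound is 0.05 — a few times
the ≈ 0.02 residual expected from 0.5° per-axis fixation noise on this
geometry — so fits contaminated by off-target samples (e.g. an attention
lapse inside a collection window) are rejected and the retry path engages
rather than silently producing a bad mapping. Monocular fits replace only
the selected eye's mapping. Fitting is deterministic, and snapshots
serialize mappings at 17 significant digits so a stored calibration
reloads bit-exactly.

## The session state machine

All interaction flows through `dispatch(state, command)`: operator
keyboard/mouse actions and controller automation use the same verbs
(enqueue, collect, discard, calibrate, snapshot, mode, eyes, auto, skip,
reward, finish), which keeps the full interface testable without any GUI
code path. Target status follows
`not_collected → enqueued → showing → collecting → {collected,
not_collected}`; enqueued points form a FIFO queue whose head is shown
whenever no point is active, and at most one point is ever
showing/collecting. Collection windows are defined in stream time (600 ms
default), not tick counts, so behavior is sampling-rate independent;
a collection succeeds when at least one selected eye contributes
`min_samples_per_point` (10) valid samples, storing *raw* positions for
calibration mode and the full sample window for validation mode. Invalid
commands are rejected with events, never exceptions, so a misbehaving
controller cannot corrupt the session.

`run_loop()` drives ticks at the nominal rate: ingest one sample, apply the
active calibration, finalize any due collection, call the controller's
`tick()` (every tick, regardless of auto mode — gating on auto is the
controller's responsibility), dispatch its commands, forward every event to
`receiveUpdate`, record status text and the draw hook's stimulus rectangle.
Rendering is abstracted to that rectangle-plus-media-id record.

## The automated NHP procedure

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `attention_duration_ms` | 30,000 | accumulated watched time before shrinking |
| `shrink_duration_ms` | 10,000 | watched time over which the video shrinks |
| `video_cal_size_px` | 300 × 300 | terminal (calibration) video size |
| `cal_points` | 2 locations | calibration layout |
| `dwell_distance_frac` | 1/3 | criterion distance, fraction of screen height |
| `dwell_duration_ms` | 500 | continuous qualifying dwell before collection |
| `val_rows` × `val_cols` | 2 × 4 | validation grid (eight points) |
| `blink_grace_samples` | 1 | invalid samples tolerated inside a dwell |
| `max_retries` | unlimited | calibration retries before giving up |

Design decisions where the procedure description left room:

- **Attention criterion** is *cumulative* watched time (gaze anywhere
  on-screen during the full-screen stage), so lapses pause rather than
  restart the phase; "approximately half a minute" is the 30 s default.
- **Shrink trajectory** is linear in size over `shrink_duration_ms` of
  watched time, pausing whenever the video is not being watched; the
  terminal size is exactly the calibration video size.
- **Dwell timer** resets on a non-qualifying valid sample; up to one
  consecutive invalid sample is tolerated (blink robustness) before the
  timer resets. The calibration-phase criterion region is a *distance from
  the video center* (a third of the vertical screen size); the
  validation-phase region is the video rectangle itself, boundary
  inclusive. Dwell uses the binocular-average gaze filtered by a 200 ms
  moving average (the procedure names temporal averaging but not a window;
  200 ms keeps dwell detection responsive at 60–600 Hz).
- **Reward** is active exactly when the filtered gaze is inside the video
  rectangle; on-screen gaze outside the video earns nothing. The manual
  reward shortcut pulses unconditionally. The sink is an abstract
  interface; the in-package implementation only records activations.
- After a successful calibration the controller deactivates itself and
  waits; the operator's confirmation (switching to validation mode and
  re-enabling auto) continues the procedure — in simulations the operator
  script of `closed_loop()` supplies exactly these actions. On calibration
  failure everything is discarded and collection restarts at point 1;
  retries are unlimited by default with a configurable cap.
- The attention phase can be skipped with the procedure's own keyboard
  command ("x"), for participants already trained to watch the screen.

The adult gaze-contingent demo uses the same dwell machinery with
arc-shaped AOIs for its ring stages: annular sectors centered on the screen
center, spanning the 120° wedge containing each target with radial bounds
at 0.5× and 1.5× the target's eccentricity (the published figure shows arcs
without dimensions; these are configurable), boundaries closed.

## The synthetic participant

`participant_model()` is the ground truth the tests measure against. Per
tick, in a fixed draw order (blink start, lapse start, four noise
deviates; an orienting-latency draw whenever the stimulus moves), it
produces: true gaze = attended stimulus center after a lognormal orienting
latency (median 250 ms), plus per-eye isotropic Gaussian fixation noise
specified in degrees (0.5° default) and converted to screen units at the
viewing distance; blinks (4/min, ~150 ms) drop validity; attention lapses
(0.02/s, ~2 s) move gaze off-screen; the tracker's *raw* report applies a
per-eye ground-truth distortion to true gaze. Blink intervals are half-open
with a microsecond tolerance so a 150 ms blink at 60 Hz is exactly 9
invalid samples regardless of tick-grid rounding. One R RNG seeded once
per stream/closed loop makes every artifact bitwise reproducible.

What the simulator does *not* emulate: saccade dynamics (gaze teleports
after the latency), pupil-size artifacts, head movement and slippage,
tracker-specific noise spectra, or distortions outside the affine family.
Passing tests therefore demonstrate that the *procedure and its
measurements* behave as specified under controlled conditions — not that
any particular animal will calibrate to a given accuracy.

## Problem sizes and numerical choices

The test suite runs the full closed loop at 60 Hz. Deterministic behavioral
checks use sessions of a few seconds; the parameter-recovery check runs
100 seeded closed-loop sessions (3° affine distortion, 0.5° noise) with the
attention phase skipped via the procedure's own skip command, measuring
post-calibration validation accuracy against the pre-calibration raw
offset; distributional checks use n = 10,000-sample streams. Stochastic
tolerances are 5% for the √2 precision-ratio and noise-recovery checks and
±2 percentage points for blink-duty data-loss recovery. Exact-arithmetic
comparisons against brute-force oracles use a 10⁻¹⁰ tolerance; angular
fixtures are constructed by inverting the angle-to-offset mapping so
stated values (e.g. "two samples 1° apart") are exact rather than
small-angle approximations.

## Limitations

The calibration stand-in is not the vendor's algorithm, and its
residual-bound failure criterion is a proxy for an undisclosed one. The
geometry assumes a planar screen facing the participant. The attention
model treats "watching" as any on-screen gaze during the full-screen
stage. Multi-monitor setups, eye-image display and real reward hardware
are out of scope; the reward interface is abstract by design.
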