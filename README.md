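# gazecal

Adaptive eye-tracker calibration and validation, hardware-free.

Screen-based eye trackers must be calibrated per participant: the tracker's
raw gaze estimate is mapped onto true screen positions using data collected
while the participant looks at known target locations, and the result is
then validated by measuring gaze quality at further known locations. With
participants who cannot follow instructions — nonhuman primates, human
infants — the operator cannot say "look at the dot": calibration has to be
*gaze-contingent*, driven by where the participant actually looks, with
attention-grabbing stimuli and (for animal work) gaze-gated rewards.

`gazecal` implements this workflow as testable software, with a synthetic
participant in place of the hardware:

- **Session state machine** — the calibration/validation interface as a
  command-driven state machine: numbered targets with an
  enqueue/show/collect/discard lifecycle, calibration computation, named
  snapshots that can be stored and restored, monocular eye selection,
  calibration vs validation modes, and an event log.
- **Controller contract** — automation plugs in through four methods
  (`tick`, `receive_update`, `get_status_text`, `draw`), called every
  frame; a controller reacts to gaze and events by issuing the same
  commands an operator would.
- **NHP procedure** — an automated three-phase controller for nonhuman
  primates: (1) attention-grabbing with a full-screen video that shrinks,
  while watched, to the 300 × 300 px calibration video; (2) dwell-triggered
  calibration: collection starts once the binocular-average gaze stays
  within one third of the vertical screen size of the video center for at
  least 500 ms (failed calibrations are discarded and recollected);
  (3) automatic validation over a 2 × 4 grid of eight points, where gaze
  must be on the video itself. Rewards are dispensed only while gaze is on
  the video. A second controller demonstrates gaze-contingent calibration
  of instructable participants via arc-shaped AOIs.
- **Data quality** — the standard metrics, per eye and for the
  binocular-average signal: accuracy (mean angular offset), RMS-S2S and
  STD precision, and data loss, per validation point and aggregated;
  plus multi-session summaries (per-participant medians with ranges,
  group means).
- **Calibration model** — a per-eye least-squares stand-in for the
  tracker's internal calibration, degrading gracefully with the number of
  usable points (1 → translation, 2 → similarity, ≥3 → affine).
- **Simulator** — a synthetic binocular participant with orienting
  latency, angular fixation noise, blinks, attention lapses and a known
  ground-truth raw-gaze distortion, so the whole closed loop runs and can
  be checked against known answers.

## Worked example

Simulate a full automated NHP session for a participant whose tracker
output is miscalibrated by a ~3° affine distortion, with 0.5° fixation
noise:

```r
library(gazecal)
g <- screen_geometry(1920, 1080, 531, 299)      # px, mm; 600 mm viewing
A <- affine_distortion(3, g)                     # ground-truth distortion
m <- participant_model(fixation_noise_sigma_deg = 0.5,
                       distortion = list(left = A, right = A), seed = 42)
out <- closed_loop(m, g, max_duration_ms = 120000)
print(out$state$active)
print(out$report)
```

```
<calibration success (both eyes)>
  left  similarity  points used: 1,2  residual RMS 0.01798
  right similarity  points used: 1,2  residual RMS 0.02003
<session_report: 8 points, 8 with data>
  aggregate accuracy (deg): L 0.585  R 0.644  avg 0.429
  aggregate RMS-S2S  (deg): L 0.965  R 0.957  avg 0.667
  aggregate data loss: L 6.6%  R 6.6%
```

The controller calibrated both eyes from the two default calibration
locations (a similarity mapping, since two points were used) and the
validation phase collected all eight grid points. The 3° miscalibration is
reduced to ~0.4–0.6° — the level set by the configured fixation noise —
and data loss reflects the simulated blinks. Group summaries in the
conventional published layout come from `summarize_sessions()`:

```r
summarize_sessions(species_accuracy_medians())$groups
#        group n_participants mean_median_acc_average
# 1 chimpanzee              6                2.266667
# 2     baboon              5                2.204000
# 3    macaque              5                1.218000
```

A YAML-configured command-line front end is included
(`inst/cli/gazecal`, subcommands `run-session`, `compute-quality`,
`summarize`, `generate-fixtures`); see `example_config_path()` for a fully
annotated configuration.

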