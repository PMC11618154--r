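# Example session configuration: a simulated nonhuman-primate
# calibration session on a 23" 1920x1080 desktop tracker setup.
screen:
  width_px: 1920
  height_px: 1080
  width_mm: 531
  height_mm: 299
  viewing_distance_mm: 600

session:
  rate_hz: 60                 # nominal tracker sampling rate (Hz)
  collection_window_ms: 600   # per-point data collection window
  min_samples_per_point: 10   # valid samples needed per point
  filter_window_ms: 200       # controller-side temporal averaging
  gaze_history_ms: 500        # operator gaze-trail window

controller:
  type: nhp
  attention_duration_ms: 30000  # ~half a minute of accumulated attention
  shrink_duration_ms: 10000     # watched time over which the video shrinks
  video_cal_size_px: [300, 300] # calibration video size
  dwell_distance_frac: 0.3333333333333333  # 1/3 of vertical screen size
  dwell_duration_ms: 500        # continuous qualifying dwell before collection
  val_rows: 2                   # validation grid: two rows ...
  val_cols: 4                   # ... by four columns (eight points)
  skip_attention: false

participant:
  fixation_noise_sigma_deg: 0.5
  latency_median_ms: 250
  blink_rate_per_min: 4
  lapse_rate_per_s: 0.02
  distortion_offset_deg: 2.0    # ground-truth raw-to-true miscalibration

seed: 1
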