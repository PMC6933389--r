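# Compact demonstration run: full temporal structure, quarter-size frames
# and a three-aldehyde panel so the whole pipeline finishes in minutes.
seed: 1
panel: [3CHO, 4CHO, 5CHO]
trials_per_stimulus: 4
acquisition:
  frame_rate_hz: 125.0
  n_frames: 1625
  frame_h: 64
  frame_w: 64
  pixel_size_um: 13.671875
  bleach_tau_s: 5.0
  bleach_fraction: 0.2
  noise_sd: 5.0
  baseline_level: 1000.0
breath:
  rate_hz: 2.0
  duty_inhale: 0.35
  jitter_sd_s: 0.02
  amplitude: 1.0
  noise_sd: 0.05
stimulus:
  requested_onset_s: 5.0
  duration_s: 2.0
  min_prestimulus_s: 4.0
  concentration_pct: 0.2
map_layout:
  n_glomeruli: 5
  ap_offset_px: 6
  radius_px: 4
  margin_px: 10
  min_sep_px: 10
  peak_amplitude: 0.08
bleach_correct:
  enabled: true
  block_size: 4
  head_frames: 480
  tail_frames: 5
  exclude_threshold: 2.0
map_windows:
  response_s: 1.6
  baseline_from_s: 1.4
  baseline_to_s: 0.4
compare:
  max_shift_px: 12
  gate_px: 5
  roi_radius_px: 3
  sigma_px: 1
  threshold_k: 3
stages:
  simulate: true
  map: true
  compare: true
write_movies: true
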