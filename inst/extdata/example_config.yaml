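# Reference sprayer rig: 3.3 m boom, two 1920x1080 cameras at 1 m,
# 22 solenoid valves at 0.15 m spacing (11 per camera), 10 Hz valves.
camera:
  image_width_px: 1920
  image_height_px: 1080
  boom_width_m: 3.3
  n_cameras: 2
  mount_height_m: 1
grille:
  n_cells: 11
  row_height_px: 60
  area_threshold_px2: 0
protocol:
  max_freq_hz: 10
  min_open_s: 0.1
simulator:
  speed_kmh: 2
  fps: 26.73
  p_detect_frame: 0.85
  detect_speed_penalty: 0.06
  sigma_loc_mm: 3
  sigma_vib0_mm: 5
  nozzle_spacing_m: 0.15
seed: 0
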