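# stereobird default system configuration
# (reference design: C1 sensor, 3 mm lens, 1 m tilted vertical baseline)

seed: 1

# chosen optical assembly
sensor: C1
focal_length: 3        # mm

# stereo rig along the baseline-aligned (portrait-mounted long) axis
rig:
  baseline: 1          # m
  vsr_axis: 3280       # px
  fov_axis: 63.0       # degrees
  tilt_alpha: 31.5     # degrees (= fov_axis / 2)

# motion-detection pipeline
detection:
  kernel: 5            # pre-blur Gaussian, odd px
  sigma: 1.5
  diff_thresh: 25      # intensity levels
  merge_kernel: 21     # ghost-merging Gaussian, odd px
  merge_sigma: 3.5
  binary_thresh: 10
  min_w: 12            # px, minimum detectable width
  min_h: 2             # px, minimum detectable height
  refine: true
  refine_thresh: 50
  crop_size: 100

# identification network
cnn:
  lc1: 32
  lc2: 32
  lfc1: 128
  lfc2: 2
  kernel: 3
  input_size: 100
  channels: 3
  learning_rate: 1.0e-5
  adam_epsilon: 1.0e-7
  epochs: 50
  validation_split: 0.1
  batch_size: 32

# size-class lower bounds (small, medium, large); below small = uncategorized
boundaries:
  wingspan: [0.68, 1.26, 1.505]   # m
  height:   [0.32, 0.40, 0.555]   # m
  area:     [0.11, 0.25, 0.415]   # m^2

# avoidance action policy (m; null disables)
policy:
  deterrent_distance: {small: 300, medium: 300, large: 300}
  stop_distance:      {small: null, medium: null, large: 200}

sync_tolerance: 0.05   # s

match:
  max_center_diff: 150 # px, false-pair filter
  min_ydiff: 1         # px, disparity floor

# candidate vision sensors
sensors:
  C1: {vsr_h: 3280, vsr_v: 2464, vss_h: 3.680, vss_v: 2.760}
  C2: {vsr_h: 4056, vsr_v: 3040, vss_h: 6.287, vss_v: 4.712}
  C3: {vsr_h: 4208, vsr_v: 3120, vss_h: 6.300, vss_v: 5.700}
  C4: {vsr_h: 4912, vsr_v: 3684, vss_h: 7.660, vss_v: 4.560}

paths:
  archive: events
  media: media
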