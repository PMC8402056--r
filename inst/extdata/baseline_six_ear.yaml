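# Easy synthetic fixture for the classical counter: six thin bright ears
# over broad leaf blades. The erosion radius (3 px) exceeds the ear
# half-width (ears are 3-4 px wide) and stays below the leaf half-width
# (blades are 12-18 px wide), so erosion-then-dilation isolates the leaf
# image and the XOR step leaves only the ears.
simulate:
  image_size: [96, 96]
  count_law: ["fixed", 6]
  overlap_fraction: 0
  ear_length: [14, 20]
  ear_width: [3, 4]
  leaves: 3
  noise_sd: 0.02
  seed: 31
baseline:
  binarize_method: otsu
  min_noise_area: 8
  erosion_radius: 3
  dilation_radius: 3
  min_ear_area: 12
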