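# Example domain specification for `wmhda_cli("simulate", ...)`.
# Keys map 1:1 onto domain_spec() arguments.
name: example
volume_shape: [32, 32, 32]
tissue_means:
  background: 0
  brain: 100
  ventricle: 40
  lesion: 170
bias_amplitude: 0.08
noise_sigma: 5
lesion_count_range: [3, 7]
lesion_radius_range: [1.6, 3.2]
periventricular_fraction: 0.5
anisotropy: [0, 0, 0]
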