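montage_name: toy-9ch
clusters:
  prefrontal: Fp1
  frontal: F3
  left_temporal: T7
  central: Cz
  right_temporal: T8
  left_parietal: P3
  mid_parietal: Pz
  right_parietal: P4
  occipital: O1
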