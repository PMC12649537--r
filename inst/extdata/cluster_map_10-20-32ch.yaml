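montage_name: 10-20-32ch
clusters:
  prefrontal:
  - Fp1
  - Fp2
  - AF3
  - AF4
  frontal:
  - F7
  - F3
  - Fz
  - F4
  - F8
  left_temporal: T7
  central:
  - FC5
  - FC1
  - C3
  - Cz
  - C4
  - FC2
  - FC6
  right_temporal: T8
  left_parietal:
  - CP5
  - CP1
  - P3
  - P7
  mid_parietal: Pz
  right_parietal:
  - CP2
  - CP6
  - P4
  - P8
  occipital:
  - PO3
  - O1
  - Oz
  - O2
  - PO4
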