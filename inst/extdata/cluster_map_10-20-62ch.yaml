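montage_name: 10-20-62ch
clusters:
  prefrontal:
  - FP1
  - FPZ
  - FP2
  - AF3
  - AF4
  frontal:
  - F7
  - F5
  - F3
  - F1
  - FZ
  - F2
  - F4
  - F6
  - F8
  left_temporal:
  - FT7
  - T7
  - TP7
  central:
  - FC5
  - FC3
  - FC1
  - FCZ
  - FC2
  - FC4
  - FC6
  - C5
  - C3
  - C1
  - CZ
  - C2
  - C4
  - C6
  right_temporal:
  - FT8
  - T8
  - TP8
  left_parietal:
  - CP5
  - CP3
  - CP1
  - P7
  - P5
  - P3
  - P1
  mid_parietal:
  - CPZ
  - PZ
  - POZ
  right_parietal:
  - CP2
  - CP4
  - CP6
  - P2
  - P4
  - P6
  - P8
  occipital:
  - PO7
  - PO5
  - PO3
  - PO4
  - PO6
  - PO8
  - CB1
  - O1
  - OZ
  - O2
  - CB2
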