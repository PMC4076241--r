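name: case2-N-linked-forward
description: Forward network inference from GlcNAcMan5GlcNAc2 (M5Gn).
binding: yes
glycans:
- id: m5gn
  file: m5gn.glycoct
enzyme_sets:
  five:
  - GnTII
  - GnTIII
  - GnTIV
  - GnTV
  - ManII
  six:
  - GnTII
  - GnTIII
  - GnTIV
  - GnTV
  - ManII
  - GalT
expected:
  five:
    species: 14
    reactions: 14
  six:
    species: 28
    reactions: 28

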