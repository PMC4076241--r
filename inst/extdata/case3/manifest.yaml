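name: case3-MS-synthetic
description: Synthetic stand-in roster of 12 N-glycan structures emulating a MALDI-TOF-annotated
  CHO-cell N-glycan list; real rosters come from external annotation pipelines and
  are supplied by the user.
binding: no
glycans:
- id: man5
  file: man5.glycoct
- id: m5gn
  file: m5gn.glycoct
- id: m3gn
  file: m3gn.glycoct
- id: gngn
  file: gngn.glycoct
- id: gngn_bis
  file: gngn_bis.glycoct
- id: gngn_f
  file: gngn_f.glycoct
- id: g1gn_f
  file: g1gn_f.glycoct
- id: g2_f
  file: g2_f.glycoct
- id: s1g2_f
  file: s1g2_f.glycoct
- id: s2g2_f
  file: s2g2_f.glycoct
- id: tri_g3_f
  file: tri_g3_f.glycoct
- id: tri_bis_f
  file: tri_bis_f.glycoct
enzymes:
- GnTI
- GnTII
- GnTIII
- GnTIV
- GnTV
- ManII
- FucT
- ST3Gal-IV
- GalT-IV
expected:
  mz_window:
  - 1400.0
  - 3300.0
  path_source: m3gn
  path_target: tri_bis_f

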