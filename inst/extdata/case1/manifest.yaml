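name: case1-O-linked-PSGL1
description: 'Core-2 trisaccharide starting glycan plus 12 observed PSGL-1 O-glycans
  (synthetic reconstruction on the core-2 scaffold: LacNAc extension, poly-LacNAc
  to 3 repeats, core-1 and LacNAc alpha2,3-sialylation, distal alpha1,3-fucosylation).
  glycan05/glycan09 carry sialyl-Lewis-X.'
binding: yes
glycans:
- id: glycan00
  file: glycan00.glycoct
- id: glycan01
  file: glycan01.glycoct
- id: glycan02
  file: glycan02.glycoct
- id: glycan03
  file: glycan03.glycoct
- id: glycan04
  file: glycan04.glycoct
- id: glycan05
  file: glycan05.glycoct
- id: glycan06
  file: glycan06.glycoct
- id: glycan07
  file: glycan07.glycoct
- id: glycan08
  file: glycan08.glycoct
- id: glycan09
  file: glycan09.glycoct
- id: glycan10
  file: glycan10.glycoct
- id: glycan11
  file: glycan11.glycoct
- id: glycan12
  file: glycan12.glycoct
enzymes:
- GalT-IV
- b3GnT
- ST3Gal-I/II
- ST3Gal-IV
- FT-VII
expected:
  species: 20
  reactions: 28
  intermediates: 7
  start: glycan00
  slex_products:
  - glycan05
  - glycan09
  subset_sweep_argmax: 6

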