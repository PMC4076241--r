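# Synthetic stand-in for an MS-annotated CHO N-glycan structure
# (illustrative; not an annotated experimental roster).
RES
1b:x-dglcnac
2b:b-dglcnac
3b:b-dman
4b:a-dman
5b:b-dglcnac
6b:b-dglcnac
7b:a-dman
8b:b-dglcnac
LIN
1:1o(4+1)2d
2:2o(4+1)3d
3:3o(3+1)4d
4:4o(2+1)5d
5:3o(4+1)6d
6:3o(6+1)7d
7:7o(2+1)8d
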