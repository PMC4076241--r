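# Synthetic stand-in for an MS-annotated CHO N-glycan structure
# (illustrative; not an annotated experimental roster).
RES
1b:x-dglcnac
2b:b-dglcnac
3b:b-dman
4b:a-dman
5b:a-dman
6b:a-dman
7b:a-dman
LIN
1:1o(4+1)2d
2:2o(4+1)3d
3:3o(3+1)4d
4:3o(6+1)5d
5:5o(3+1)6d
6:5o(6+1)7d
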