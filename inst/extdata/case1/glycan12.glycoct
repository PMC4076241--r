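# Synthetic reconstruction of a PSGL-1 O-glycan (core-2 scaffold).
# Reconstruction on the core-2 scaffold; structural ambiguities
# resolved toward reproducing the reference 20-species / 28-reaction
# connection network (see fixture manifest).
RES
1b:x-dgalnac
2b:b-dgal
3b:a-dneu5ac
4b:b-dglcnac
5b:b-dgal
6b:b-dglcnac
7b:b-dgal
8b:b-dglcnac
9b:b-dgal
LIN
1:1o(3+1)2d
2:2o(3+2)3d
3:1o(6+1)4d
4:4o(4+1)5d
5:5o(3+1)6d
6:6o(4+1)7d
7:7o(3+1)8d
8:8o(4+1)9d
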