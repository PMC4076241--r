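# Synthetic stand-in for an MS-annotated CHO N-glycan structure
# (illustrative; not an annotated experimental roster).
RES
1b:x-dglcnac
2b:b-dglcnac
3b:b-dman
4b:a-dman
5b:b-dglcnac
6b:b-dgal
7b:a-dneu5ac
8b:a-dman
9b:b-dglcnac
10b:b-dgal
11b:a-dneu5ac
12b:a-lfuc
LIN
1:1o(4+1)2d
2:2o(4+1)3d
3:3o(3+1)4d
4:4o(2+1)5d
5:5o(4+1)6d
6:6o(3+2)7d
7:3o(6+1)8d
8:8o(2+1)9d
9:9o(4+1)10d
10:10o(3+2)11d
11:1o(6+1)12d
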