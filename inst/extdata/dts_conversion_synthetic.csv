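utci_c,dts
-40,-3
-27,-2.5
-13,-1.9
0,-1.2
9,-0.5
18,-0.1
26,0.6
32,1.4
38,2.2
46,3
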