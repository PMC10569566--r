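times_sighted,count
1,1021
2,420
3,166
4,50
5,20
6,6
7,1
8,0
9,0
10,0
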