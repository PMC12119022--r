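month,temp_c
1,2.1
2,1.8
3,3.4
4,6.9
5,11.3
6,15.2
7,17.4
8,17.1
9,14.2
10,10.1
11,6.2
12,3.3
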