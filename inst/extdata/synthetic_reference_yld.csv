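band,yld_rate
0-5,0.075
5-10,0.060
10-15,0.060
15-20,0.070
20-25,0.080
25-30,0.090
30-35,0.100
35-40,0.110
40-45,0.120
45-50,0.135
50-55,0.150
55-75,0.185
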