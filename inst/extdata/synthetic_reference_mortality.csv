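band,band_start,band_end,rate
0-5,0,5,0.01425
5-10,5,10,0.00182
10-15,10,15,0.00125
15-20,15,20,0.00160
20-25,20,25,0.00239
25-30,25,30,0.00331
30-35,30,35,0.00433
35-40,35,40,0.00536
40-45,40,45,0.00661
45-50,45,50,0.00855
50-55,50,55,0.01117
55-75,55,75,0.03306
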