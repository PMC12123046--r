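age_lo	age_hi	population
0	9	1050000
10	19	1052000
20	29	1139000
30	39	1409000
40	49	1396000
50	59	1392000
60	69	1224000
70	79	808000
80	89	443000
90	99	87000
100	104	2000
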