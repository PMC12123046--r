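age,q_male,q_female
0,0.00055256478,0.00055256478
1,0.00055722818,0.00055722818
2,0.00056230529,0.00056230529
3,0.00056783283,0.00056783283
4,0.00057385076,0.00057385076
5,0.00058040259,0.00058040259
6,0.00058753567,0.00058753567
7,0.00059530158,0.00059530158
8,0.00060375645,0.00060375645
9,0.00061296142,0.00061296142
10,0.00062298303,0.00062298303
11,0.00063389372,0.00063389372
12,0.00064577238,0.00064577238
13,0.00065870488,0.00065870488
14,0.00067278471,0.00067278471
15,0.00068811366,0.00068811366
16,0.00070480255,0.00070480255
17,0.00072297203,0.00072297203
18,0.00074275346,0.00074275346
19,0.00076428983,0.00076428983
20,0.00078773685,0.00078773685
21,0.00081326402,0.00081326402
22,0.00084105589,0.00084105589
23,0.00087131337,0.00087131337
24,0.0009042552,0.0009042552
25,0.00094011953,0.00094011953
26,0.00097916565,0.00097916565
27,0.0010216758,0.0010216758
28,0.0010679574,0.0010679574
29,0.0011183449,0.0011183449
30,0.0011732026,0.0011732026
31,0.0012329272,0.0012329272
32,0.0012979503,0.0012979503
33,0.0013687421,0.0013687421
34,0.0014458144,0.0014458144
35,0.0015297243,0.0015297243
36,0.0016210784,0.0016210784
37,0.0017205372,0.0017205372
38,0.0018288197,0.0018288197
39,0.0019467086,0.0019467086
40,0.0020750564,0.0020750564
41,0.0022147908,0.0022147908
42,0.002366922,0.002366922
43,0.0025325498,0.0025325498
44,0.0027128717,0.0027128717
45,0.0029091912,0.0029091912
46,0.0031229275,0.0031229275
47,0.003355626,0.003355626
48,0.0036089687,0.0036089687
49,0.0038847873,0.0038847873
50,0.0041850757,0.0041850757
51,0.0045120048,0.0045120048
52,0.0048679381,0.0048679381
53,0.0052554488,0.0052554488
54,0.0056773383,0.0056773383
55,0.0061366565,0.0061366565
56,0.0066367242,0.0066367242
57,0.0071811563,0.0071811563
58,0.0077738889,0.0077738889
59,0.008419207,0.008419207
60,0.0091217758,0.0091217758
61,0.0098866745,0.0098866745
62,0.010719433,0.010719433
63,0.011626071,0.011626071
64,0.012613143,0.012613143
65,0.013687786,0.013687786
66,0.014857767,0.014857767
67,0.016131546,0.016131546
68,0.017518331,0.017518331
69,0.019028148,0.019028148
70,0.020671911,0.020671911
71,0.022461503,0.022461503
72,0.024409864,0.024409864
73,0.026531077,0.026531077
74,0.028840477,0.028840477
75,0.031354761,0.031354761
76,0.034092105,0.034092105
77,0.037072298,0.037072298
78,0.040316885,0.040316885
79,0.043849323,0.043849323
80,0.047695147,0.047695147
81,0.051882162,0.051882162
82,0.056440637,0.056440637
83,0.061403526,0.061403526
84,0.066806709,0.066806709
85,0.072689245,0.072689245
86,0.079093663,0.079093663
87,0.086066263,0.086066263
88,0.093657451,0.093657451
89,0.10192211,0.10192211
90,0.11091998,0.11091998
91,0.12071611,0.12071611
92,0.13138134,0.13138134
93,0.14299274,0.14299274
94,0.15563428,0.15563428
95,0.16939734,0.16939734
96,0.18438142,0.18438142
97,0.20069484,0.20069484
98,0.21845554,0.21845554
99,0.23779191,0.23779191
100,0.25884375,0.25884375
101,0.28176325,0.28176325
102,0.30671611,0.30671611
103,0.3338827,0.3338827
104,0.36345943,0.36345943
105,0.39566013,0.39566013
106,0.43071758,0.43071758
107,0.46888522,0.46888522
108,0.51043898,0.51043898
109,0.55567927,0.55567927
110,0.60493315,0.60493315
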