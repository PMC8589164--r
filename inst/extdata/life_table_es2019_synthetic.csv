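age,qx
0,1.9786365e-05
1,2.1773466e-05
2,2.3960124e-05
3,2.6366381e-05
4,2.9014289e-05
5,3.1928115e-05
6,3.5134564e-05
7,3.8663021e-05
8,4.2545822e-05
9,4.6818552e-05
10,5.1520366e-05
11,5.6694352e-05
12,6.2387925e-05
13,6.865326e-05
14,7.554777e-05
15,8.3134633e-05
16,9.1483369e-05
17,0.00010067048
18,0.00011078014
19,0.00012190499
20,0.00013414695
21,0.00014761819
22,0.00016244211
23,0.00017875454
24,0.00019670489
25,0.0002164576
26,0.00023819361
27,0.00026211199
28,0.00028843181
29,0.0003173941
30,0.00034926407
31,0.00038433353
32,0.00042292356
33,0.00046538741
34,0.00051211378
35,0.00056353031
36,0.00062010748
37,0.00068236293
38,0.00075086614
39,0.00082624363
40,0.00090918462
41,0.0010004473
42,0.0011008658
43,0.0012113576
44,0.0013329317
45,0.0014666984
46,0.0016138783
47,0.0017758143
48,0.001953983
49,0.0021500083
50,0.0023656756
51,0.0026029483
52,0.0028639849
53,0.003151158
54,0.0034670761
55,0.0038146058
56,0.0041968974
57,0.0046174126
58,0.0050799545
59,0.0055887005
60,0.0061482386
61,0.0067636068
62,0.0074403353
63,0.008184494
64,0.0090027431
65,0.0099023878
66,0.010891439
67,0.011978678
68,0.013173726
69,0.01448712
70,0.015930398
71,0.017516179
72,0.019258266
73,0.021171739
74,0.023273065
75,0.025580213
76,0.028112767
77,0.030892056
78,0.033941281
79,0.037285651
80,0.040952513
81,0.044971495
82,0.049374637
83,0.054196525
84,0.059474408
85,0.065248312
86,0.071561127
87,0.078458671
88,0.085989721
89,0.094205998
90,0.1031621
91,0.11291534
92,0.12352555
93,0.13505473
94,0.14756658
95,0.16112592
96,0.17579788
97,0.19164694
98,0.20873571
99,0.22712348
100,1
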