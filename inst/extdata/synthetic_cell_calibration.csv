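"opacity","cells"
0.5,15
2.31,71.3
4.11,129.1
5.92,191.6
7.73,253.1
9.53,318.7
11.34,383
13.15,458.3
14.95,522.4
16.76,599
18.57,678.4
20.38,757.5
22.18,835.9
23.99,928
25.8,1008.2
27.6,1094.3
29.41,1180.4
31.22,1284.3
33.02,1359.7
34.83,1503.8
36.64,1562.2
38.44,1683.2
40.25,1779.2
42.06,1895.6
43.86,1973
45.67,2090.9
47.48,2197.5
49.28,2333.8
51.09,2418.1
52.9,2572.8
54.7,2685.8
56.51,2862.9
58.32,2936
60.12,3065.2
61.93,3178.3
63.74,3326.8
65.55,3476.7
67.35,3623.2
69.16,3789
70.97,3929.9
72.77,4032.4
74.58,4243.3
76.39,4257.8
78.19,4513.5
80,4615.8
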