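region_id	name	hemisphere	lobe
1	roi_001_L	L	parietal
2	roi_002_L	L	parietal
3	roi_003_L	L	parietal
4	roi_004_L	L	parietal
5	roi_005_L	L	temporal
6	roi_006_L	L	temporal
7	roi_007_L	L	temporal
8	roi_008_L	L	parietal
9	roi_009_L	L	frontal
10	roi_010_L	L	parietal
11	roi_011_L	L	parietal
12	roi_012_L	L	parietal
13	roi_013_L	L	parietal
14	roi_014_L	L	temporal
15	roi_015_L	L	temporal
16	roi_016_L	L	temporal
17	roi_017_L	L	temporal
18	roi_018_L	L	occipital
19	roi_019_L	L	parietal
20	roi_020_L	L	frontal
21	roi_021_L	L	parietal
22	roi_022_L	L	parietal
23	roi_023_L	L	parietal
24	roi_024_L	L	parietal
25	roi_025_L	L	parietal
26	roi_026_L	L	temporal
27	roi_027_L	L	temporal
28	roi_028_L	L	temporal
29	roi_029_L	L	temporal
30	roi_030_L	L	occipital
31	roi_031_L	L	occipital
32	roi_032_L	L	frontal
33	roi_033_L	L	frontal
34	roi_034_L	L	parietal
35	roi_035_L	L	parietal
36	roi_036_L	L	parietal
37	roi_037_L	L	parietal
38	roi_038_L	L	parietal
39	roi_039_L	L	temporal
40	roi_040_L	L	temporal
41	roi_041_L	L	temporal
42	roi_042_L	L	temporal
43	roi_043_L	L	occipital
44	roi_044_L	L	temporal
45	roi_045_L	L	frontal
46	roi_046_L	L	parietal
47	roi_047_L	L	parietal
48	roi_048_L	L	parietal
49	roi_049_L	L	parietal
50	roi_050_L	L	temporal
51	roi_051_L	L	temporal
52	roi_052_L	L	temporal
53	roi_053_L	L	temporal
54	roi_054_L	L	occipital
55	roi_055_L	L	parietal
56	roi_056_L	L	parietal
57	roi_057_L	L	parietal
58	roi_058_L	L	parietal
59	roi_059_L	L	temporal
60	roi_060_L	L	temporal
61	roi_061_L	L	temporal
62	roi_062_L	L	temporal
63	roi_001_R	R	parietal
64	roi_002_R	R	parietal
65	roi_003_R	R	parietal
66	roi_004_R	R	parietal
67	roi_005_R	R	temporal
68	roi_006_R	R	temporal
69	roi_007_R	R	temporal
70	roi_008_R	R	parietal
71	roi_009_R	R	frontal
72	roi_010_R	R	parietal
73	roi_011_R	R	parietal
74	roi_012_R	R	parietal
75	roi_013_R	R	parietal
76	roi_014_R	R	temporal
77	roi_015_R	R	temporal
78	roi_016_R	R	temporal
79	roi_017_R	R	temporal
80	roi_018_R	R	occipital
81	roi_019_R	R	parietal
82	roi_020_R	R	frontal
83	roi_021_R	R	parietal
84	roi_022_R	R	parietal
85	roi_023_R	R	parietal
86	roi_024_R	R	parietal
87	roi_025_R	R	parietal
88	roi_026_R	R	temporal
89	roi_027_R	R	temporal
90	roi_028_R	R	temporal
91	roi_029_R	R	temporal
92	roi_030_R	R	occipital
93	roi_031_R	R	occipital
94	roi_032_R	R	frontal
95	roi_033_R	R	frontal
96	roi_034_R	R	parietal
97	roi_035_R	R	parietal
98	roi_036_R	R	parietal
99	roi_037_R	R	parietal
100	roi_038_R	R	parietal
101	roi_039_R	R	temporal
102	roi_040_R	R	temporal
103	roi_041_R	R	temporal
104	roi_042_R	R	temporal
105	roi_043_R	R	occipital
106	roi_044_R	R	temporal
107	roi_045_R	R	frontal
108	roi_046_R	R	parietal
109	roi_047_R	R	parietal
110	roi_048_R	R	parietal
111	roi_049_R	R	parietal
112	roi_050_R	R	temporal
113	roi_051_R	R	temporal
114	roi_052_R	R	temporal
115	roi_053_R	R	temporal
116	roi_054_R	R	occipital
117	roi_055_R	R	parietal
118	roi_056_R	R	parietal
119	roi_057_R	R	parietal
120	roi_058_R	R	parietal
121	roi_059_R	R	temporal
122	roi_060_R	R	temporal
123	roi_061_R	R	temporal
124	roi_062_R	R	temporal
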