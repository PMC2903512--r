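# Synthetic unisex period life table (frozen fixture).
# Gompertz-Makeham annual hazard h(x) = 2e-4 + 2.78e-5 * exp(0.092 * x);
# annual_death_prob = 1 - exp(-h(x)).  Calibrated to values typical of
# Canadian unisex life tables of the late 2000s (q(54) ~ 0.004, q(80) ~ 0.044).
# Columns: age (years), annual_death_prob.
age	annual_death_prob
35	0.0008954
36	0.0009624
37	0.0010358
38	0.0011163
39	0.0012046
40	0.0013013
41	0.0014074
42	0.0015237
43	0.0016511
44	0.0017909
45	0.001944
46	0.0021119
47	0.002296
48	0.0024977
49	0.0027189
50	0.0029613
51	0.003227
52	0.0035182
53	0.0038373
54	0.0041872
55	0.0045705
56	0.0049907
57	0.0054511
58	0.0059557
59	0.0065086
60	0.0071144
61	0.0077782
62	0.0085054
63	0.0093021
64	0.0101749
65	0.0111308
66	0.0121778
67	0.0133245
68	0.0145801
69	0.0159548
70	0.0174599
71	0.0191073
72	0.0209103
73	0.0228833
74	0.0250418
75	0.0274028
76	0.0299847
77	0.0328077
78	0.0358931
79	0.0392647
80	0.0429475
81	0.0469691
82	0.0513587
83	0.0561482
84	0.0613713
85	0.0670646
86	0.0732669
87	0.0800195
88	0.0873662
89	0.0953535
90	0.1040302
91	0.1134474
92	0.1236584
93	0.1347183
94	0.1466836
95	0.1596119
96	0.1735611
97	0.1885885
98	0.2047502
99	0.2220996
100	0.2406862
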