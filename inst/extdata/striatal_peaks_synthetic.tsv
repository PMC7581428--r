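sample_id	repeat_units	height
WT_m01	111	987.2
WT_m01	123	1.01
WT_m01	126	2.32
WT_m01	127	0.98
WT_m01	128	3.02
WT_m01	129	2.87
WT_m01	130	9.52
WT_m01	131	7.73
WT_m01	132	18.81
WT_m01	133	24.19
WT_m01	134	34.58
WT_m01	135	40.65
WT_m01	136	48.72
WT_m01	137	46.52
WT_m01	138	55.26
WT_m01	139	82.89
WT_m01	140	74.75
WT_m01	141	62.03
WT_m01	142	86.99
WT_m01	143	71.14
WT_m01	144	54.24
WT_m01	145	52.98
WT_m01	146	40.53
WT_m01	147	51.64
WT_m01	148	31.93
WT_m01	149	24.5
WT_m01	150	23.47
WT_m01	151	26.09
WT_m01	152	10.13
WT_m01	153	7.01
WT_m01	154	5.62
WT_m01	155	4
WT_m01	156	3.06
WT_m01	157	1.9
WT_m01	158	1.87
WT_m01	162	0.92
WT_m01	168	1.03
WT_m02	111	1034.71
WT_m02	124	0.99
WT_m02	125	1.97
WT_m02	128	4.62
WT_m02	129	2.1
WT_m02	130	12.82
WT_m02	131	17.7
WT_m02	132	21.84
WT_m02	133	18.65
WT_m02	134	32.23
WT_m02	135	41.57
WT_m02	136	37.57
WT_m02	137	58.07
WT_m02	138	53.46
WT_m02	139	64.33
WT_m02	140	72.46
WT_m02	141	75
WT_m02	142	61.46
WT_m02	143	72.32
WT_m02	144	67.82
WT_m02	145	46.42
WT_m02	146	55.54
WT_m02	147	33.68
WT_m02	148	32.34
WT_m02	149	23.53
WT_m02	150	13.74
WT_m02	151	20.49
WT_m02	152	8.54
WT_m02	153	12.78
WT_m02	154	6.19
WT_m02	155	2.95
WT_m02	156	1.82
WT_m02	160	1.04
WT_m03	111	961.05
WT_m03	127	2.02
WT_m03	128	0.98
WT_m03	129	3.02
WT_m03	130	6.32
WT_m03	131	12.02
WT_m03	132	12.63
WT_m03	133	28.18
WT_m03	134	26.81
WT_m03	135	45.06
WT_m03	136	49.14
WT_m03	137	56.62
WT_m03	138	74.8
WT_m03	139	64.4
WT_m03	140	88
WT_m03	141	65.63
WT_m03	142	61.32
WT_m03	143	79.15
WT_m03	144	76.38
WT_m03	145	51.63
WT_m03	146	51.72
WT_m03	147	44.69
WT_m03	148	23.1
WT_m03	149	32.52
WT_m03	150	21.79
WT_m03	151	19.78
WT_m03	152	17.32
WT_m03	153	3.1
WT_m03	154	8.07
WT_m03	155	3.92
WT_m03	156	2.06
WT_m03	157	2.95
WT_m03	158	4.17
WT_m03	159	2.1
WT_m03	161	0.97
KO_m01	111	1016.2
KO_m01	121	1.09
KO_m01	123	0.98
KO_m01	124	1.86
KO_m01	125	5.71
KO_m01	126	12.91
KO_m01	127	12.85
KO_m01	128	14.23
KO_m01	129	26.6
KO_m01	130	41.59
KO_m01	131	53.73
KO_m01	132	63.48
KO_m01	133	64.67
KO_m01	134	71.86
KO_m01	135	78.71
KO_m01	136	79.66
KO_m01	137	67.53
KO_m01	138	51.23
KO_m01	139	64.99
KO_m01	140	63.05
KO_m01	141	51.3
KO_m01	142	31.52
KO_m01	143	31.21
KO_m01	144	28.65
KO_m01	145	19.79
KO_m01	146	17.9
KO_m01	147	8.51
KO_m01	148	3.88
KO_m01	149	3.85
KO_m01	150	1.94
KO_m01	151	0.96
KO_m01	152	0.99
KO_m01	153	0.88
KO_m02	111	1036.26
KO_m02	121	0.99
KO_m02	123	2.1
KO_m02	124	2.01
KO_m02	125	4.61
KO_m02	126	16.9
KO_m02	127	15.29
KO_m02	128	20.37
KO_m02	129	34.34
KO_m02	130	35.78
KO_m02	131	50.14
KO_m02	132	57.38
KO_m02	133	60.99
KO_m02	134	83.41
KO_m02	135	69.23
KO_m02	136	80.86
KO_m02	137	83.72
KO_m02	138	77.76
KO_m02	139	72.28
KO_m02	140	61.8
KO_m02	141	47.98
KO_m02	142	52.6
KO_m02	143	29.95
KO_m02	144	16.19
KO_m02	145	17.44
KO_m02	146	13.67
KO_m02	147	5.12
KO_m02	148	5.74
KO_m02	149	4.18
KO_m02	150	2.09
KO_m02	152	0.91
KO_m02	155	2.14
KO_m02	157	2.15
KO_m02	161	1
KO_m03	111	1008.87
KO_m03	123	2.03
KO_m03	125	4.75
KO_m03	126	8.69
KO_m03	127	17.24
KO_m03	128	15.89
KO_m03	129	26.96
KO_m03	130	25.03
KO_m03	131	46.37
KO_m03	132	59.5
KO_m03	133	51.25
KO_m03	134	64.82
KO_m03	135	72.96
KO_m03	136	72.69
KO_m03	137	75.96
KO_m03	138	70.14
KO_m03	139	74.87
KO_m03	140	62.49
KO_m03	141	46.99
KO_m03	142	40.38
KO_m03	143	46.12
KO_m03	144	26.9
KO_m03	145	22.25
KO_m03	146	19.37
KO_m03	147	13.83
KO_m03	148	4.68
KO_m03	149	5.79
KO_m03	150	6.42
KO_m03	151	1.05
KO_m03	153	1.06
KO_m03	154	1.86
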