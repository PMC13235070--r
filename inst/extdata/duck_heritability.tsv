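line	trait	h2_g	h2_g_se	h2_a	h2_a_se	ratio
A	JW	0.23	0.01	0.41	0.02	0.56
A	BW	0.33	0.01	0.31	0.02	1.06
A	BD	0.17	0.01	0.22	0.02	0.77
A	PRF	0.25	0.01	0.31	0.02	0.81
A	GAIT	0.07	0.01	0.10	0.01	0.70
A	ADG	0.17	0.01	0.13	0.01	1.31
A	FPD	0.25	0.01	0.30	0.02	0.83
D	JW	0.25	0.01	0.46	0.02	0.54
D	BW	0.37	0.02	0.50	0.02	0.74
D	BD	0.15	0.01	0.21	0.02	0.71
D	PRF	0.19	0.01	0.26	0.02	0.73
D	GAIT	0.07	0.01	0.10	0.01	0.70
D	ADG	0.22	0.01	0.31	0.02	0.71
D	FPD	0.21	0.01	0.25	0.02	0.84
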