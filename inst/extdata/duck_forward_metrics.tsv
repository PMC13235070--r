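line	trait	matrix	h2	se	r	acc	b	b_std
A	JW	G	0.25	0.02	0.24	0.49	0.81	0.19
A	BW	G	0.32	0.02	0.39	0.68	1.02	-0.02
A	BD	G	0.20	0.02	0.22	0.50	0.89	0.11
A	PRF	G	0.24	0.02	0.34	0.69	0.99	0.01
A	GAIT	G	0.06	0.01	0.14	0.58	1.02	-0.02
A	ADG	G	0.15	0.01	0.25	0.65	1.10	-0.09
A	FPD	G	0.26	0.02	0.34	0.68	0.99	0.01
A	JW	A	0.44	0.03	0.16	0.24	0.59	0.41
A	BW	A	0.36	0.03	0.21	0.35	0.92	0.08
A	BD	A	0.23	0.02	0.13	0.26	0.72	0.28
A	PRF	A	0.31	0.03	0.22	0.40	0.94	0.06
A	GAIT	A	0.08	0.01	0.07	0.24	0.75	0.25
A	ADG	A	0.11	0.02	0.13	0.40	1.22	-0.18
A	FPD	A	0.29	0.03	0.23	0.44	0.98	0.02
D	JW	G	0.27	0.02	0.29	0.55	0.91	0.09
D	BW	G	0.40	0.02	0.44	0.69	0.97	0.03
D	BD	G	0.17	0.02	0.21	0.50	0.83	0.17
D	PRF	G	0.25	0.03	0.29	0.58	0.98	0.02
D	GAIT	G	0.06	0.02	0.13	0.51	0.92	0.08
D	ADG	G	0.28	0.03	0.30	0.56	0.93	0.07
D	FPD	G	0.21	0.05	0.33	0.73	1.08	-0.07
D	JW	A	0.46	0.03	0.26	0.38	0.83	0.17
D	BW	A	0.55	0.03	0.29	0.39	0.92	0.08
D	BD	A	0.21	0.02	0.13	0.28	0.63	0.37
D	PRF	A	0.18	0.02	0.19	0.44	1.01	-0.01
D	GAIT	A	0.10	0.02	0.08	0.26	0.92	0.08
D	ADG	A	0.34	0.03	0.12	0.21	0.72	0.28
D	FPD	A	0.23	0.03	0.22	0.47	0.99	0.01
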