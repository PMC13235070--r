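line	trait	n	mean	sd	skewness	kurtosis	cv	se
A	JW	13610	567.15	86.27	-0.30	0.24	15.21	0.74
A	BW	13640	4009.88	361.95	0.09	-0.23	9.03	3.10
A	BD	11875	17.85	2.34	0.14	0.21	13.10	0.02
A	PRF	11900	78.84	11.53	-0.76	1.38	14.63	0.11
A	GAIT	13635	3.15	0.66	-0.14	0.41	20.82	0.01
A	ADG	13638	144.53	18.99	0.19	0.18	13.14	0.16
A	FPD	12126	1.99	0.80	0.67	0.34	40.00	0.01
D	JW	13020	524.21	66.12	-0.17	0.26	12.61	0.06
D	BW	13020	3204.60	294.20	0.11	-0.26	9.18	2.58
D	BD	11241	21.56	2.88	-0.08	-0.13	13.35	0.03
D	PRF	11277	105.12	11.85	-1.56	4.89	11.27	0.11
D	GAIT	13012	3.10	0.61	0.15	0.87	19.57	0.01
D	ADG	13020	96.80	15.85	0.09	-0.23	16.37	0.14
D	FPD	10693	1.94	0.66	0.24	-0.08	34.10	0.01
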