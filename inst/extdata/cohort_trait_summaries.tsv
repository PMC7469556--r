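sex	trait	mean_control	sd_control	mean_case	sd_case	p_printed
F	Age	65.80	13.64	64.12	8.15	0.65
F	Weight_kg	52.10	10.17	63.12	16.06	0.02
F	BMI	21.49	4.02	26.31	6.96	0.02
F	Waist_hip_ratio	0.97	0.07	0.99	0.10	0.50
F	Fasting_glucose	90.42	12.48	183.32	72.45	0.00007
F	Triglyceride	163.70	79.26	154.65	53.17	0.68
F	Total_cholesterol	195.60	42.19	182.04	35.58	0.30
F	HDL	40.90	8.83	41.61	4.00	0.75
F	LDL	87.39	20.63	93.05	21.91	0.43
F	VLDL	31.71	8.44	51.09	40.88	0.07
F	Serum_creatinine	1.04	0.32	1.04	0.38	1.00
F	HOMA_B	192.89	252.9	115.68	125.97	0.24
F	HOMA_IR	2.45	2.13	12.30	11.38	0.002
F	Insulin	11.16	9.89	26.22	19.00	0.01
F	HbA1c	5.45	0.62	8.17	1.38	0.0000002
F	NEFA	0.62	0.30	0.63	0.48	0.92
F	hsCRP	7950.78	5701.0	8769.12	4779.9	0.64
F	Leptin	8150.77	7945.67	19144.99	27723.65	0.13
F	Adiponectin	210.71	116.19	236.74	239.48	0.69
F	IL_6	33.33	53.05	30.53	33.71	0.85
F	TNF_alpha	25.42	17.51	28.84	35.04	0.72
M	Age	61.95	9.07	58.87	9.17	0.33
M	Weight_kg	55.80	6.92	63.07	11.02	0.04
M	BMI	20.28	2.80	22.73	3.25	0.03
M	Waist_hip_ratio	1.03	0.21	1.03	0.07	0.90
M	Fasting_glucose	88.96	9.69	204.36	102.13	0.0006
M	Triglyceride	154.32	44.02	144.57	55.02	0.59
M	Total_cholesterol	180.65	37.41	192.63	66.90	0.56
M	HDL	40.47	4.43	40.21	7.62	0.91
M	LDL	94.28	19.16	95.69	33.11	0.89
M	VLDL	31.22	6.79	33.92	10.65	0.44
M	Serum_creatinine	0.99	0.17	1.08	0.20	0.22
M	HOMA_B	132.87	87.65	126.59	126.75	0.87
M	HOMA_IR	1.83	1.47	11.97	7.16	0.00007
M	Insulin	8.25	5.93	24.44	10.77	0.00003
M	HbA1c	5.32	0.55	9.22	2.75	0.00007
M	NEFA	0.51	0.26	0.66	0.43	0.26
M	hsCRP	7279.16	5140.79	10202.27	4134.99	0.07
M	Leptin	7810.80	5691.17	8094.73	6584.18	0.89
M	Adiponectin	183.76	117.78	208.99	86.46	0.47
M	IL_6	22.02	29.45	30.34	46.60	0.55
M	TNF_alpha	32.70	29.63	28.75	35.79	0.73
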