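mtp	source	feature	q1	m	q3
1	MEA	SR	2.71	9.53	36.26
1	MEA	BR	0.07	0.26	1.08
1	MEA	BD	0.87	5.25	12.65
1	MEA	SB	1.57	3.16	4.96
2	MEA	SR	8.11	16.99	49.30
2	MEA	BR	0.09	0.39	0.99
2	MEA	BD	1.50	2.50	9.65
2	MEA	SB	2.00	5.00	11.40
3	MEA	SR	14.92	39.45	144.64
3	MEA	BR	0.88	1.42	5.22
3	MEA	BD	2.05	6.98	7.55
3	MEA	SB	3.08	6.33	7.62
4	MEA	SR	57.10	91.21	163.21
4	MEA	BR	0.89	4.19	7.19
4	MEA	BD	0.97	2.79	4.45
4	MEA	SB	4.16	7.00	19.31
5	MEA	SR	109.76	148.48	224.46
5	MEA	BR	4.29	5.66	10.69
5	MEA	BD	2.35	3.71	16.23
5	MEA	SB	12.18	18.67	45.68
6	MEA	SR	53.68	106.90	113.65
6	MEA	BR	2.24	2.59	4.79
6	MEA	BD	1.44	12.68	17.97
6	MEA	SB	7.19	20.00	24.68
1	INEX	SR	10.98	11.39	11.98
1	INEX	BR	0.28	0.40	0.57
1	INEX	BD	13.99	18.09	21.43
1	INEX	SB	4.15	5.61	6.38
2	INEX	SR	14.19	15.67	17.74
2	INEX	BR	0.40	0.47	0.62
2	INEX	BD	6.85	10.17	27.46
2	INEX	SB	4.02	4.56	10.95
3	INEX	SR	23.04	24.17	26.15
3	INEX	BR	0.42	0.60	0.84
3	INEX	BD	11.87	16.56	18.36
3	INEX	SB	7.00	9.01	10.47
4	INEX	SR	56.02	57.16	60.39
4	INEX	BR	2.28	2.67	3.15
4	INEX	BD	10.05	11.14	12.65
4	INEX	SB	13.07	14.94	16.46
5	INEX	SR	95.83	100.71	104.10
5	INEX	BR	4.60	5.34	6.26
5	INEX	BD	4.18	5.13	5.93
5	INEX	SB	11.43	13.37	14.15
6	INEX	SR	49.64	54.16	56.28
6	INEX	BR	1.63	2.06	2.46
6	INEX	BD	9.67	12.96	15.75
6	INEX	SB	12.57	15.14	17.97
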