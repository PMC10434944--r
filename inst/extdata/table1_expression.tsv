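transcript	S1	S2	S3	S4	S5
R59489	75.46	34.91	26.16	95.97	46.3
R119018	62.21	15.2	32.65	78.32	24.22
R105494	4.68	8.23	6.23	33.16	23.61
R105492	53.58	5.34	5.74	22.35	15.69
R96316	17.42	10.16	5.09	25.07	15.07
R172551	4.37	0	4.57	0.84	0
R72448	57.97	17.85	25.64	47.21	86.91
R71730	0.99	3.49	0	3.22	1.68
R177267	55.45	15.3	17.07	71.99	21.71
R207525	62.77	51.93	41.84	68.5	40.72
R215855	93.83	86.79	63.09	144.09	46.63
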