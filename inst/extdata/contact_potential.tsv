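aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.25	-0.145	0.235	0.185	-0.43	-0.205	0.075	-0.49	0.425	-0.39	-0.255	0.195	-0.09	0.22	0.775	0.005	-0.035	-0.395	-0.31	-0.135
C	-0.145	-0.04	0.34	0.29	-0.325	-0.1	0.18	-0.385	0.53	-0.285	-0.15	0.3	0.015	0.325	0.88	0.11	0.07	-0.29	-0.205	-0.03
D	0.235	0.34	0.72	0.67	0.055	0.28	0.56	-0.005	0.91	0.095	0.23	0.68	0.395	0.705	1.26	0.49	0.45	0.09	0.175	0.35
E	0.185	0.29	0.67	0.62	0.005	0.23	0.51	-0.055	0.86	0.045	0.18	0.63	0.345	0.655	1.21	0.44	0.4	0.04	0.125	0.3
F	-0.43	-0.325	0.055	0.005	-0.61	-0.385	-0.105	-0.67	0.245	-0.57	-0.435	0.015	-0.27	0.04	0.595	-0.175	-0.215	-0.575	-0.49	-0.315
G	-0.205	-0.1	0.28	0.23	-0.385	-0.16	0.12	-0.445	0.47	-0.345	-0.21	0.24	-0.045	0.265	0.82	0.05	0.01	-0.35	-0.265	-0.09
H	0.075	0.18	0.56	0.51	-0.105	0.12	0.4	-0.165	0.75	-0.065	0.07	0.52	0.235	0.545	1.1	0.33	0.29	-0.07	0.015	0.19
I	-0.49	-0.385	-0.005	-0.055	-0.67	-0.445	-0.165	-0.73	0.185	-0.63	-0.495	-0.045	-0.33	-0.02	0.535	-0.235	-0.275	-0.635	-0.55	-0.375
K	0.425	0.53	0.91	0.86	0.245	0.47	0.75	0.185	1.1	0.285	0.42	0.87	0.585	0.895	1.45	0.68	0.64	0.28	0.365	0.54
L	-0.39	-0.285	0.095	0.045	-0.57	-0.345	-0.065	-0.63	0.285	-0.53	-0.395	0.055	-0.23	0.08	0.635	-0.135	-0.175	-0.535	-0.45	-0.275
M	-0.255	-0.15	0.23	0.18	-0.435	-0.21	0.07	-0.495	0.42	-0.395	-0.26	0.19	-0.095	0.215	0.77	0	-0.04	-0.4	-0.315	-0.14
N	0.195	0.3	0.68	0.63	0.015	0.24	0.52	-0.045	0.87	0.055	0.19	0.64	0.355	0.665	1.22	0.45	0.41	0.05	0.135	0.31
P	-0.09	0.015	0.395	0.345	-0.27	-0.045	0.235	-0.33	0.585	-0.23	-0.095	0.355	0.07	0.38	0.935	0.165	0.125	-0.235	-0.15	0.025
Q	0.22	0.325	0.705	0.655	0.04	0.265	0.545	-0.02	0.895	0.08	0.215	0.665	0.38	0.69	1.245	0.475	0.435	0.075	0.16	0.335
R	0.775	0.88	1.26	1.21	0.595	0.82	1.1	0.535	1.45	0.635	0.77	1.22	0.935	1.245	1.8	1.03	0.99	0.63	0.715	0.89
S	0.005	0.11	0.49	0.44	-0.175	0.05	0.33	-0.235	0.68	-0.135	0	0.45	0.165	0.475	1.03	0.26	0.22	-0.14	-0.055	0.12
T	-0.035	0.07	0.45	0.4	-0.215	0.01	0.29	-0.275	0.64	-0.175	-0.04	0.41	0.125	0.435	0.99	0.22	0.18	-0.18	-0.095	0.08
V	-0.395	-0.29	0.09	0.04	-0.575	-0.35	-0.07	-0.635	0.28	-0.535	-0.4	0.05	-0.235	0.075	0.63	-0.14	-0.18	-0.54	-0.455	-0.28
W	-0.31	-0.205	0.175	0.125	-0.49	-0.265	0.015	-0.55	0.365	-0.45	-0.315	0.135	-0.15	0.16	0.715	-0.055	-0.095	-0.455	-0.37	-0.195
Y	-0.135	-0.03	0.35	0.3	-0.315	-0.09	0.19	-0.375	0.54	-0.275	-0.14	0.31	0.025	0.335	0.89	0.12	0.08	-0.28	-0.195	-0.02
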