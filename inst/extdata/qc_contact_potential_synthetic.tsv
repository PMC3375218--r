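	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-2.72	-4.08	-1.965	-1.815	-4.99	-2.48	-2.885	-4.63	-1.42	-4.88	-4.09	-2.2	-2.235	-2.13	-2.135	-2.195	-2.42	-4.12	-3.89	-3.445
C	-4.08	-5.44	-3.325	-3.175	-6.35	-3.84	-4.245	-5.99	-2.78	-6.24	-5.45	-3.56	-3.595	-3.49	-3.495	-3.555	-3.78	-5.48	-5.25	-4.805
D	-1.965	-3.325	-1.21	-1.06	-4.235	-1.725	-2.13	-3.875	-0.665	-4.125	-3.335	-1.445	-1.48	-1.375	-1.38	-1.44	-1.665	-3.365	-3.135	-2.69
E	-1.815	-3.175	-1.06	-0.91	-4.085	-1.575	-1.98	-3.725	-0.515	-3.975	-3.185	-1.295	-1.33	-1.225	-1.23	-1.29	-1.515	-3.215	-2.985	-2.54
F	-4.99	-6.35	-4.235	-4.085	-7.26	-4.75	-5.155	-6.9	-3.69	-7.15	-6.36	-4.47	-4.505	-4.4	-4.405	-4.465	-4.69	-6.39	-6.16	-5.715
G	-2.48	-3.84	-1.725	-1.575	-4.75	-2.24	-2.645	-4.39	-1.18	-4.64	-3.85	-1.96	-1.995	-1.89	-1.895	-1.955	-2.18	-3.88	-3.65	-3.205
H	-2.885	-4.245	-2.13	-1.98	-5.155	-2.645	-3.05	-4.795	-1.585	-5.045	-4.255	-2.365	-2.4	-2.295	-2.3	-2.36	-2.585	-4.285	-4.055	-3.61
I	-4.63	-5.99	-3.875	-3.725	-6.9	-4.39	-4.795	-6.54	-3.33	-6.79	-6	-4.11	-4.145	-4.04	-4.045	-4.105	-4.33	-6.03	-5.8	-5.355
K	-1.42	-2.78	-0.665	-0.515	-3.69	-1.18	-1.585	-3.33	-0.12	-3.58	-2.79	-0.9	-0.935	-0.83	-0.835	-0.895	-1.12	-2.82	-2.59	-2.145
L	-4.88	-6.24	-4.125	-3.975	-7.15	-4.64	-5.045	-6.79	-3.58	-7.04	-6.25	-4.36	-4.395	-4.29	-4.295	-4.355	-4.58	-6.28	-6.05	-5.605
M	-4.09	-5.45	-3.335	-3.185	-6.36	-3.85	-4.255	-6	-2.79	-6.25	-5.46	-3.57	-3.605	-3.5	-3.505	-3.565	-3.79	-5.49	-5.26	-4.815
N	-2.2	-3.56	-1.445	-1.295	-4.47	-1.96	-2.365	-4.11	-0.9	-4.36	-3.57	-1.68	-1.715	-1.61	-1.615	-1.675	-1.9	-3.6	-3.37	-2.925
P	-2.235	-3.595	-1.48	-1.33	-4.505	-1.995	-2.4	-4.145	-0.935	-4.395	-3.605	-1.715	-1.75	-1.645	-1.65	-1.71	-1.935	-3.635	-3.405	-2.96
Q	-2.13	-3.49	-1.375	-1.225	-4.4	-1.89	-2.295	-4.04	-0.83	-4.29	-3.5	-1.61	-1.645	-1.54	-1.545	-1.605	-1.83	-3.53	-3.3	-2.855
R	-2.135	-3.495	-1.38	-1.23	-4.405	-1.895	-2.3	-4.045	-0.835	-4.295	-3.505	-1.615	-1.65	-1.545	-1.55	-1.61	-1.835	-3.535	-3.305	-2.86
S	-2.195	-3.555	-1.44	-1.29	-4.465	-1.955	-2.36	-4.105	-0.895	-4.355	-3.565	-1.675	-1.71	-1.605	-1.61	-1.67	-1.895	-3.595	-3.365	-2.92
T	-2.42	-3.78	-1.665	-1.515	-4.69	-2.18	-2.585	-4.33	-1.12	-4.58	-3.79	-1.9	-1.935	-1.83	-1.835	-1.895	-2.12	-3.82	-3.59	-3.145
V	-4.12	-5.48	-3.365	-3.215	-6.39	-3.88	-4.285	-6.03	-2.82	-6.28	-5.49	-3.6	-3.635	-3.53	-3.535	-3.595	-3.82	-5.52	-5.29	-4.845
W	-3.89	-5.25	-3.135	-2.985	-6.16	-3.65	-4.055	-5.8	-2.59	-6.05	-5.26	-3.37	-3.405	-3.3	-3.305	-3.365	-3.59	-5.29	-5.06	-4.615
Y	-3.445	-4.805	-2.69	-2.54	-5.715	-3.205	-3.61	-5.355	-2.145	-5.605	-4.815	-2.925	-2.96	-2.855	-2.86	-2.92	-3.145	-4.845	-4.615	-4.17
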