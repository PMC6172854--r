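subject	n200LatencyMs.EO	n200AmpUV.EO	p300LatencyMs.EO	p300AmpUV.EO	n200LatencyMs.EC	n200AmpUV.EC	p300LatencyMs.EC	p300AmpUV.EC
S1	197	-2.42	792	2.41	206	-1.70	310	2.32
S2	230	-0.65	808	1.53	203	-0.87	428	3.73
S3	150	-0.23	740	0.80	150	-0.50	805	0.81
S4	195	-0.82	796	1.99	197	-0.41	346	2.93
S5	237	-1.85	390	1.81	244	-1.91	437	1.96
S6	169	-0.41	704	1.19	179	-1.04	561	0.89
S7	239	-2.36	615	2.09	250	-2.08	543	2.01
S8	220	-1.27	840	1.86	212	-1.60	512	1.64
S9	195	-2.02	755	1.94	221	-1.46	687	1.91
S10	213	-1.28	359	1.84	223	-1.37	339	1.25
S11	190	-3.53	742	1.59	190	-2.92	570	1.81
S12	179	-1.48	743	1.47	195	-3.23	742	2.11
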