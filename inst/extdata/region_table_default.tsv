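id	abbreviation	name	hemisphere
0	LCC	left corpus callosum	L
1	LCB	left cerebellum	L
2	LSUC	left superior colliculus, motor related	L
3	LHY	left hypothalamus	L
4	LIC	left inferior colliculus	L
5	LCOA	left cortical amygdalar area	L
6	LMO	left somatomotor cortex	L
7	LSS	left somatosensory cortex	L
8	LPIR	left piriform cortex	L
9	LTT	left taenia tecta	L
10	LRHP	left retrohippocampal region	L
11	LMB	left midbrain	L
12	LCA1	left hippocampal field CA1	L
13	LCA2	left hippocampal field CA2	L
14	LCA3	left hippocampal field CA3	L
15	LDG	left dentate gyrus	L
16	LEC	left entorhinal cortex	L
17	LTH	left thalamus	L
18	LICtx	left isocortex	L
19	LMY	left medulla	L
20	LP	left pons	L
21	LPL01	left synthetic placeholder parcel 1	L
22	LPL02	left synthetic placeholder parcel 2	L
23	LPL03	left synthetic placeholder parcel 3	L
24	LPL04	left synthetic placeholder parcel 4	L
25	LPL05	left synthetic placeholder parcel 5	L
26	LPL06	left synthetic placeholder parcel 6	L
27	LPL07	left synthetic placeholder parcel 7	L
28	LPL08	left synthetic placeholder parcel 8	L
29	LPL09	left synthetic placeholder parcel 9	L
30	LPL10	left synthetic placeholder parcel 10	L
31	LPL11	left synthetic placeholder parcel 11	L
32	LPL12	left synthetic placeholder parcel 12	L
33	LPL13	left synthetic placeholder parcel 13	L
34	LPL14	left synthetic placeholder parcel 14	L
35	LPL15	left synthetic placeholder parcel 15	L
36	RCC	right corpus callosum	R
37	RCB	right cerebellum	R
38	RSUC	right superior colliculus, motor related	R
39	RHY	right hypothalamus	R
40	RIC	right inferior colliculus	R
41	RCOA	right cortical amygdalar area	R
42	RMO	right somatomotor cortex	R
43	RSS	right somatosensory cortex	R
44	RPIR	right piriform cortex	R
45	RTT	right taenia tecta	R
46	RRHP	right retrohippocampal region	R
47	RMB	right midbrain	R
48	RCA1	right hippocampal field CA1	R
49	RCA2	right hippocampal field CA2	R
50	RCA3	right hippocampal field CA3	R
51	RDG	right dentate gyrus	R
52	REC	right entorhinal cortex	R
53	RTH	right thalamus	R
54	RICtx	right isocortex	R
55	RMY	right medulla	R
56	RP	right pons	R
57	RPL01	right synthetic placeholder parcel 1	R
58	RPL02	right synthetic placeholder parcel 2	R
59	RPL03	right synthetic placeholder parcel 3	R
60	RPL04	right synthetic placeholder parcel 4	R
61	RPL05	right synthetic placeholder parcel 5	R
62	RPL06	right synthetic placeholder parcel 6	R
63	RPL07	right synthetic placeholder parcel 7	R
64	RPL08	right synthetic placeholder parcel 8	R
65	RPL09	right synthetic placeholder parcel 9	R
66	RPL10	right synthetic placeholder parcel 10	R
67	RPL11	right synthetic placeholder parcel 11	R
68	RPL12	right synthetic placeholder parcel 12	R
69	RPL13	right synthetic placeholder parcel 13	R
70	RPL14	right synthetic placeholder parcel 14	R
71	RPL15	right synthetic placeholder parcel 15	R
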