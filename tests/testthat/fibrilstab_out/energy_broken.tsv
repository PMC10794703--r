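resno	resid	fragment	energy
12	LEU	N	-0.367749600041465
13	MET	N	-0.839226211924056
14	VAL	N	-0.796073295234347
15	LYS	N	-0.818516833151592
16	VAL	N	-0.808837586185882
17	LEU	N	-0.820979841792006
18	ASP	N	-0.820423779892321
19	ALA	N	-0.825905859072835
20	VAL	N	-0.83200997359876
21	ARG	N	-0.878181960828569
22	GLY	N	-0.408900275013287
23	SER	N	-0.811432541717747
24	PRO	N	-0.757183519775558
25	ALA	N	-0.791279224844968
26	ILE	N	-0.802733471659957
27	ASN	N	-0.858094617401516
28	VAL	N	-0.820979841792006
29	ALA	N	-0.876340987533566
30	VAL	N	-0.818516833151592
31	HIS	N	-0.842311255909881
32	VAL	N	-0.819138868497003
33	PHE	N	-0.845330326449981
34	ARG	N	-0.819138868497003
35	LYS	N	-0.991301287506377
64	PHE	C	-0.328541476527114
65	VAL	C	-0.830725062203442
66	GLU	C	-0.832566035498445
67	GLY	C	-0.401379302200593
68	ILE	C	-0.790591216053832
69	TYR	C	-0.836207141383956
70	LYS	C	-0.798536303874761
71	VAL	C	-0.832566035498446
72	GLU	C	-0.805196480300371
73	ILE	C	-0.832566035498446
74	ASP	C	-0.829546964958346
75	THR	C	-0.81678267400681
76	LYS	C	-0.83200997359876
77	SER	C	-0.786950110168322
78	TYR	C	-0.820555726783772
79	TRP	C	-0.787638118959458
80	LYS	C	-0.768213651582312
81	ALA	C	-0.785175110319044
82	LEU	C	-0.855009573415691
83	GLY	C	-0.441513148350202
84	SER	C	-0.827640018217617
85	SER	C	-0.860557626041931
86	PRO	C	-0.809393648085567
87	PHE	C	-0.851434440975906
88	HIS	C	-0.810015683430978
89	GLU	C	-0.854453511516006
90	HIS	C	-0.819138868497003
91	ALA	C	-0.827083956317931
92	GLU	C	-0.819138868497003
93	VAL	C	-0.824620947677517
94	VAL	C	-0.898269304255622
95	PHE	C	-0.7796678983973
96	THR	C	-0.864861607977348
97	ALA	C	-0.837492052779274
98	ASN	C	-0.799158339220172
99	ASP	C	-0.833188070843856
100	SER	C	-0.830103026858031
101	GLY	C	-0.412965495907032
102	PRO	C	-0.799714401119857
103	ARG	C	-0.820423779892321
104	ARG	C	-0.832566035498446
105	TYR	C	-0.832566035498446
106	THR	C	-0.811300594826296
107	ILE	C	-0.814319665366396
108	ALA	C	-0.829546964958346
109	ALA	C	-0.799092365774446
110	LEU	C	-0.845462273341432
111	LEU	C	-0.777892898548022
112	SER	C	-0.771854757467823
113	PRO	C	-0.785175110319043
114	TYR	C	-0.793610286593932
115	SER	C	-0.867217802467541
116	TYR	C	-0.793610286593932
117	SER	C	-0.860557626041931
118	THR	C	-0.820423779892321
119	THR	C	-0.868502713862859
120	ALA	C	-0.826527894418246
121	VAL	C	-0.85691652015642
122	VAL	C	-0.980893191045034
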