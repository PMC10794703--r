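resno	resid	fragment	energy
11	PRO	N	-0.558383536656396
12	LEU	N	-0.822091965591377
13	MET	N	-0.865310855726812
14	VAL	N	-0.767418828640954
15	LYS	N	-0.824686921123242
16	VAL	N	-0.85389744961632
17	LEU	N	-0.810081656876703
18	ASP	N	-0.843423379709252
19	ALA	N	-0.811300594826296
20	VAL	N	-0.861669749841301
21	ARG	N	-0.854519484961731
22	GLY	N	-0.438003989356142
23	SER	N	-0.82093900108751
24	PRO	N	-0.754164449235459
25	ALA	N	-0.798005374716304
26	ILE	N	-0.792881437098299
27	ASN	N	-0.862291785186712
28	VAL	N	-0.833744132743542
29	ALA	N	-0.85691652015642
30	VAL	N	-0.842311255909881
31	HIS	N	-0.832632008944171
32	VAL	N	-0.825242983022928
33	PHE	N	-0.878181960828569
34	ARG	N	-0.859828776546298
35	LYS	N	-1.01620783406404
60	THR	C	-0.275284150665908
61	GLU	C	-0.848971432335491
62	GLU	C	-0.726000071096026
63	GLU	C	-0.877453111332936
64	PHE	C	-0.743068343982979
65	VAL	C	-0.883067137404901
66	GLU	C	-0.864198731927441
67	GLY	C	-0.396519258365489
68	ILE	C	-0.773522943166879
69	TYR	C	-0.888549216585416
70	LYS	C	-0.789306304658514
71	VAL	C	-0.882935190513451
72	GLU	C	-0.833188070843856
73	ILE	C	-0.828752142016987
74	ASP	C	-0.824064885777831
75	THR	C	-0.864688820381401
76	LYS	C	-0.834366168088952
77	SER	C	-0.835585106038545
78	TYR	C	-0.782156039778944
79	TRP	C	-0.785175110319043
80	LYS	C	-0.776051925253019
81	ALA	C	-0.794986304176204
82	LEU	C	-0.908397798970796
83	GLY	C	-0.412409434007346
84	SER	C	-0.830659088757716
85	SER	C	-0.917137709733083
86	PRO	C	-0.830103026858031
87	PHE	C	-0.861735723287027
88	HIS	C	-0.88182306671408
89	GLU	C	-0.853168600120687
90	HIS	C	-0.878738022728255
91	ALA	C	-0.779561084247079
92	GLU	C	-0.872699881648055
93	VAL	C	-0.834300194643227
94	VAL	C	-0.901910410141133
95	PHE	C	-0.813697630020985
96	THR	C	-0.893343286974794
97	ALA	C	-0.865483643322759
98	ASN	C	-0.788684269313103
99	ASP	C	-0.913945851597035
100	SER	C	-0.833744132743542
101	GLY	C	-0.431039078443134
102	PRO	C	-0.834300194643227
103	ARG	C	-0.855009573415691
104	ARG	C	-0.820489753338046
105	TYR	C	-0.858650679301202
106	THR	C	-0.837385238629052
107	ILE	C	-0.840404309169152
108	ALA	C	-0.870170899561915
109	ALA	C	-0.771788784022097
110	LEU	C	-0.82458010697302
111	LEU	C	-0.779070995793118
112	SER	C	-0.785175110319044
113	PRO	C	-0.873453863884917
114	TYR	C	-0.814875727266081
115	SER	C	-0.846508423695077
116	TYR	C	-0.797807454379128
117	SER	C	-0.842867317809566
118	THR	C	-0.824064885777831
119	THR	C	-0.87880399617398
120	ALA	C	-0.811749842575759
121	VAL	C	-0.835478291888323
122	VAL	C	-0.873812005447426
123	THR	C	-0.829546964958346
124	ASN	C	-1.03882415957723
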