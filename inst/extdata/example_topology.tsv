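#helix	I	37	62
#helix	II	74	98
#helix	III	110	132
#helix	IV	153	177
#helix	V	192	216
#helix	VI	346	370
#helix	VII	379	403
bead_id	molecule_id	molecule_kind	receptor_id	residue_index	bead_role	helix_label
1	1	receptor	1	40	backbone	I
2	1	receptor	1	44	backbone	I
3	1	receptor	1	48	backbone	I
4	1	receptor	1	52	backbone	I
5	1	receptor	1	56	backbone	I
6	1	receptor	1	48	sidechain	I
7	1	receptor	1	78	backbone	II
8	1	receptor	1	82	backbone	II
9	1	receptor	1	86	backbone	II
10	1	receptor	1	90	backbone	II
11	1	receptor	1	94	backbone	II
12	1	receptor	1	86	sidechain	II
13	1	receptor	1	112	backbone	III
14	1	receptor	1	116	backbone	III
15	1	receptor	1	120	backbone	III
16	1	receptor	1	124	backbone	III
17	1	receptor	1	128	backbone	III
18	1	receptor	1	120	sidechain	III
19	1	receptor	1	156	backbone	IV
20	1	receptor	1	160	backbone	IV
21	1	receptor	1	164	backbone	IV
22	1	receptor	1	167	backbone	IV
23	1	receptor	1	172	backbone	IV
24	1	receptor	1	164	sidechain	IV
25	1	receptor	1	196	backbone	V
26	1	receptor	1	200	backbone	V
27	1	receptor	1	204	backbone	V
28	1	receptor	1	208	backbone	V
29	1	receptor	1	212	backbone	V
30	1	receptor	1	204	sidechain	V
31	1	receptor	1	350	backbone	VI
32	1	receptor	1	354	backbone	VI
33	1	receptor	1	358	backbone	VI
34	1	receptor	1	362	backbone	VI
35	1	receptor	1	366	backbone	VI
36	1	receptor	1	358	sidechain	VI
37	1	receptor	1	382	backbone	VII
38	1	receptor	1	386	backbone	VII
39	1	receptor	1	390	backbone	VII
40	1	receptor	1	394	backbone	VII
41	1	receptor	1	398	backbone	VII
42	1	receptor	1	390	sidechain	VII
43	1	receptor	1	250	backbone	loop
44	1	receptor	1	260	backbone	loop
45	2	receptor	2	40	backbone	I
46	2	receptor	2	44	backbone	I
47	2	receptor	2	48	backbone	I
48	2	receptor	2	52	backbone	I
49	2	receptor	2	56	backbone	I
50	2	receptor	2	48	sidechain	I
51	2	receptor	2	78	backbone	II
52	2	receptor	2	82	backbone	II
53	2	receptor	2	86	backbone	II
54	2	receptor	2	90	backbone	II
55	2	receptor	2	94	backbone	II
56	2	receptor	2	86	sidechain	II
57	2	receptor	2	112	backbone	III
58	2	receptor	2	116	backbone	III
59	2	receptor	2	120	backbone	III
60	2	receptor	2	124	backbone	III
61	2	receptor	2	128	backbone	III
62	2	receptor	2	120	sidechain	III
63	2	receptor	2	156	backbone	IV
64	2	receptor	2	160	backbone	IV
65	2	receptor	2	164	backbone	IV
66	2	receptor	2	167	backbone	IV
67	2	receptor	2	172	backbone	IV
68	2	receptor	2	164	sidechain	IV
69	2	receptor	2	196	backbone	V
70	2	receptor	2	200	backbone	V
71	2	receptor	2	204	backbone	V
72	2	receptor	2	208	backbone	V
73	2	receptor	2	212	backbone	V
74	2	receptor	2	204	sidechain	V
75	2	receptor	2	350	backbone	VI
76	2	receptor	2	354	backbone	VI
77	2	receptor	2	358	backbone	VI
78	2	receptor	2	362	backbone	VI
79	2	receptor	2	366	backbone	VI
80	2	receptor	2	358	sidechain	VI
81	2	receptor	2	382	backbone	VII
82	2	receptor	2	386	backbone	VII
83	2	receptor	2	390	backbone	VII
84	2	receptor	2	394	backbone	VII
85	2	receptor	2	398	backbone	VII
86	2	receptor	2	390	sidechain	VII
87	2	receptor	2	250	backbone	loop
88	2	receptor	2	260	backbone	loop
89	3	POPC	NA	NA	phosphate	NA
90	3	POPC	NA	NA	other	NA
91	3	POPC	NA	NA	other	NA
92	4	POPC	NA	NA	phosphate	NA
93	4	POPC	NA	NA	other	NA
94	4	POPC	NA	NA	other	NA
95	5	POPC	NA	NA	phosphate	NA
96	5	POPC	NA	NA	other	NA
97	5	POPC	NA	NA	other	NA
98	6	CHOL	NA	NA	other	NA
99	6	CHOL	NA	NA	other	NA
100	7	CHOL	NA	NA	other	NA
101	7	CHOL	NA	NA	other	NA
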