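# Per-step local helix parameters (ASSP output) for the TM2 helical region
# (residues 51-87) of mitochondrial cytochrome-c oxidase, PDB 1v55 chain A.
# One row per 4-CA window; step = author residue number of CA1; aa = one-letter
# code of that residue. Values transcribed at the published 1-decimal precision.
step	aa	twist	rise	vtor	bend	radius
51	D	101.9	1.4	48.0	94.0	2.3
52	Q	100.7	1.5	52.2	166.5	2.3
53	I	100.1	1.4	48.6	9.5	2.3
54	Y	100.4	1.5	51.6	3.6	2.3
55	N	100.0	1.5	51.3	3.4	2.3
56	V	98.3	1.5	47.5	3.9	2.3
57	V	97.3	1.5	48.6	2.5	2.3
58	V	94.6	1.4	43.8	2.2	2.4
59	T	103.7	1.7	60.1	7.8	2.2
60	A	94.9	1.4	44.2	11.8	2.4
61	H	96.2	1.5	47.6	12.0	2.3
62	A	95.6	1.5	47.7	8.8	2.4
63	F	94.6	1.5	45.0	3.8	2.4
64	V	87.1	1.3	36.0	4.1	2.6
65	M	79.7	1.0	25.1	5.8	2.8
66	I	80.9	1.2	31.3	9.9	2.8
67	F	74.8	1.1	25.9	4.9	3.0
68	F	78.8	1.4	33.4	0.2	2.8
69	M	89.2	1.5	41.6	6.1	2.5
70	V	96.6	1.5	49.0	4.1	2.3
71	M	92.7	1.5	44.1	4.4	2.4
72	P	86.1	1.4	37.0	4.9	2.6
73	I	79.5	0.8	21.1	9.2	2.9
74	M	85.6	1.3	34.5	14.4	2.6
75	I	82.8	1.2	32.5	12.2	2.7
76	G	81.8	0.9	23.5	15.5	2.8
77	G	99.7	1.7	55.5	19.8	2.2
78	F	92.3	1.3	40.4	19.5	2.5
79	G	93.7	1.5	45.2	19.3	2.4
80	N	78.3	1.1	26.5	4.3	2.9
81	W	97.7	2.2	67.3	20.8	2.0
82	L	93.9	1.4	43.0	27.2	2.4
83	V	98.7	1.5	48.8	31.9	2.3
84	P	99.6	1.7	55.7	25.6	2.2
85	L	91.3	1.2	36.6	15.0	2.5
86	M	227.9	2.6	247.0	94.2	1.5
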