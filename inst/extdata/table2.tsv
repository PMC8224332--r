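no	gene_name	locus_id	subfamily	subgroup	h2	h5	le1	le2	location
1	CaPIP1;1	CA.PGAv.1.6.scaffold890.5	PIP	PIP1	F	H	T	R	chr02
2	CaPIP1;2	CA.PGAv.1.6.scaffold216.2	PIP	PIP1	F	H	T	R	chr10
3	CaPIP1;3	CA.PGAv.1.6.scaffold588.86	PIP	PIP1	F	H	T	R	PGAv.1.6.scaffold588
4	CaPIP2;1	CANN_MIP.chr06.1	PIP	PIP2	-	H	T	R	chr06
5	CaPIP2;2	CA.PGAv.1.6.scaffold920.3	PIP	PIP2	F	-	-	-	chr06
6	CaPIP2;3	CA.PGAv.1.6.scaffold888.8	PIP	PIP2	F	H	T	R	chr09
7	CaPIP2;4	CA.PGAv.1.6.scaffold888.7	PIP	PIP2	F	H	T	R	chr09
8	CaPIP2;5	CA.PGAv.1.6.scaffold888.6	PIP	PIP2	F	H	T	R	chr09
9	CaPIP2;6	CA.PGAv.1.6.scaffold1169.2	PIP	PIP2	F	H	T	R	chr10
10	CaPIP2;7	CA.PGAv.1.6.scaffold631.27	PIP	PIP2	F	H	T	R	chr11
11	CaPIP3;1	CA.PGAv.1.6.scaffold774.55	PIP	PIP3	F	H	T	R	chr01
12	CaPIP3;2	CA.PGAv.1.6.scaffold792.78	PIP	PIP3	F	H	T	R	chr01
13	CaPIP3;3	CA.PGAv.1.6.scaffold613.1	PIP	PIP3	L	Y	T	R	chr03
14	CaPIP3;4	CA.PGAv.1.6.scaffold1184.2	PIP	PIP3	F	H	T	R	chr05
15	CaPIP3;5	CA.PGAv.1.6.scaffold78.85	PIP	PIP3	F	H	T	R	chr08
16	CaPIP3;6	CA.PGAv.1.6.scaffold815.3	PIP	PIP3	F	H	T	R	chr12
17	CaPIP3;7	CA.PGAv.1.6.scaffold855.26	PIP	PIP3	F	H	T	R	PGAv.1.6.scaffold855
18	CaPIP3;8	CA.PGAv.1.6.scaffold855.28	PIP	PIP3	-	P	I	G	PGAv.1.6.scaffold855
19	CaPIP3;9	CANN_MIP.PGAv.1.6.scaffold855.1	PIP	PIP3	-	P	I	R	PGAv.1.6.scaffold855
20	CaTIP1;1	CA.PGAv.1.6.scaffold610.69	TIP	TIP1	H	I	A	R	chr11
21	CaTIP2;1	CA.PGAv.1.6.scaffold1058.46	TIP	TIP2	-	I	G	R	chr01
22	CaTIP2;2	CA.PGAv.1.6.scaffold48.31	TIP	TIP2	N	V	G	Y	chr03
23	CaTIP2;3	CA.PGAv.1.6.scaffold438.40	TIP	TIP2	H	I	G	R	chr03
24	CaTIP2;4	CA.PGAv.1.6.scaffold62.35	TIP	TIP2	H	I	G	R	chr06
25	CaTIP2;5	CA.PGAv.1.6.scaffold1152.13	TIP	TIP2	H	I	G	R	chr06
26	CaTIP3;1	CA.PGAv.1.6.scaffold861.16	TIP	TIP3	H	V	A	R	chr03
27	CaTIP3;2	CA.PGAv.1.6.scaffold65.60	TIP	TIP3	H	V	A	R	chr06
28	CaTIP4;1	CA.PGAv.1.6.scaffold298.3	TIP	TIP4	H	T	A	M	chr01
29	CaTIP4;2	CA.PGAv.1.6.scaffold298.4	TIP	TIP4	H	T	A	M	chr01
30	CaTIP4;3	CA.PGAv.1.6.scaffold298.5	TIP	TIP4	-	T	A	M	chr01
31	CaTIP4;4	CANN_MIP.chr01.3	TIP	TIP4	H	-	Q	F	chr01
32	CaTIP4;5	CA.PGAv.1.6.scaffold298.6	TIP	TIP4	M	V	Y	G	chr01
33	CaTIP4;6	CA.PGAv.1.6.scaffold777.2	TIP	TIP4	H	-	-	-	chr01
34	CaTIP4;7	CA.PGAv.1.6.scaffold777.1	TIP	TIP4	H	L	A	M	chr01
35	CaTIP4;8	CANN_MIP.chr01.1	TIP	TIP4	H	T	A	M	chr01
36	CaTIP4;9	CA.PGAv.1.6.scaffold1381.7	TIP	TIP4	H	N	A	M	chr01
37	CaTIP4;10	CA.PGAv.1.6.scaffold1432.12	TIP	TIP4	H	I	A	V	chr06
38	CaTIP4;11	CA.PGAv.1.6.scaffold394.19	TIP	TIP4	H	I	A	V	chr06
39	CaTIP4;12	CA.PGAv.1.6.scaffold467.1	TIP	TIP4	H	I	A	G	chr07
40	CaTIP4;13	CANN_MIP.chr01.2	TIP	TIP4	H	T	A	M	chr01
41	CaTIP4;14	CA.PGAv.1.6.scaffold488.29	TIP	TIP4	H	I	A	V	chr10
42	CaTIP4;15	CA.PGAv.1.6.scaffold820.9	TIP	TIP4	-	I	A	M	chr11
43	CaTIP4;16	CA.PGAv.1.6.scaffold420.10	TIP	TIP4	H	V	A	L	chr11
44	CaTIP4;17	CA.PGAv.1.6.scaffold1381.8	TIP	TIP4	H	T	A	M	chr01
45	CaTIP4;18	CA.PGAv.1.6.scaffold280.18	TIP	TIP4	H	I	A	M	chr11
46	CaTIP4;19	CA.PGAv.1.6.scaffold1381.9	TIP	TIP4	H	T	A	M	chr01
47	CaTIP4;20	CA.PGAv.1.6.scaffold963.13	TIP	TIP4	-	I	A	M	PGAv.1.6.scaffold963
48	CaTIP4;21	CA.PGAv.1.6.scaffold1331.1	TIP	TIP4	H	-	-	G	PGAv.1.6.scaffold1331
49	CaTIP4;22	CA.PGAv.1.6.scaffold298.1	TIP	TIP4	H	T	A	M	chr01
50	CaTIP4;23	CA.PGAv.1.6.scaffold298.2	TIP	TIP4	H	T	A	M	chr01
51	CaNIP1;1	CA.PGAv.1.6.scaffold38.2	NIP	NIP1	A	V	-	-	chr01
52	CaNIP1;2	CA.PGAv.1.6.scaffold792.10	NIP	NIP1	A	I	G	R	chr01
53	CaNIP1;3	CA.PGAv.1.6.scaffold407.53	NIP	NIP1	S	I	A	R	chr03
54	CaNIP3;1	CA.PGAv.1.6.scaffold1545.1	NIP	NIP3	W	V	A	R	chr02
55	CaNIP3;2	CA.PGAv.1.6.scaffold1067.9	NIP	NIP3	W	-	-	-	chr02
56	CaNIP3;3	CA.PGAv.1.6.scaffold411.30	NIP	NIP3	W	V	A	R	chr02
57	CaNIP3;4	CA.PGAv.1.6.scaffold411.29	NIP	NIP3	W	S	A	R	chr02
58	CaNIP3;5	CA.PGAv.1.6.scaffold625.87	NIP	NIP3	W	V	A	R	chr02
59	CaNIP3;6	CANN_MIP.chr03.1	NIP	NIP3	W	-	-	-	chr03
60	CaNIP3;7	CANN_MIP.chr05.1	NIP	NIP3	W	-	-	R	chr05
61	CaNIP3;8	CA.PGAv.1.6.scaffold65.202	NIP	NIP3	W	-	-	K	chr06
62	CaNIP3;9	CA.PGAv.1.6.scaffold65.203	NIP	NIP3	W	I	A	R	chr06
63	CaNIP3;10	CA.PGAv.1.6.scaffold1298.6	NIP	NIP3	-	V	A	R	chr11
64	CaNIP3;11	CANN_MIP.chr11.1	NIP	NIP3	W	D	S	S	chr11
65	CaNIP3;12	CA.PGAv.1.6.scaffold1122.2	NIP	NIP3	W	A	-	K	chr12
66	CaNIP3;13	CA.PGAv.1.6.scaffold1569.5	NIP	NIP3	W	V	A	R	PGAv.1.6.scaffold1569
67	CaSIP1;1	CANN_MIP.chr01.4	SIP	SIP1	-	-	S	S	chr01
68	CaSIP1;2	CA.PGAv.1.6.scaffold245.6	SIP	SIP1	I	-	G	S	chr01
69	CaSIP1;3	CA.PGAv.1.6.scaffold415.6	SIP	SIP1	I	-	P	N	chr03
70	CaSIP1;4	CANN_MIP.chr07.1	SIP	SIP1	-	-	-	-	chr07
71	CaSIP1;5	CA.PGAv.1.6.scaffold960.54	SIP	SIP1	L	-	P	N	PGAv.1.6.scaffold960
72	CaXIP1;1	CA.PGAv.1.6.scaffold564.27	XIP	XIP1	I	T	A	R	chr04
73	CaXIP1;2	CA.PGAv.1.6.scaffold588.13	XIP	XIP1	I	T	A	R	PGAv.1.6.scaffold588
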