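cohort_id	country	age_stratum	n_initial	n_available	n_caesarean	n_vaginal	mean_age_months
COPSAC	Denmark	m1_2	505	303	72	231	1
HOUSTON	USA	m1_2	52	48	11	37	1.5
INFANTMET	Ireland	m1_2	167	137	65	72	1
JORVI	Finland	m1_2	68	51	8	43	1
NHBCS	USA	m1_2	321	319	92	227	1.5
NOMIC	Norway	m1_2	485	485	159	326	1
WHEALS	USA	m1_2	130	114	33	81	1.2
INFANTMET	Ireland	m3_6	152	152	86	66	5.5
JORVI	Finland	m3_6	68	62	10	52	6
MARC-43	USA	m3_6	115	115	43	72	3.4
WHEALS	USA	m3_6	167	144	62	82	6.6
ABIS	Sweden	m9_12	403	399	47	352	12
COPSAC	Denmark	m9_12	623	424	90	334	12
JORVI	Finland	m9_12	62	62	10	52	12
NHBCS	USA	m9_12	135	135	38	97	12
NOMIC	Norway	m9_12	340	340	103	237	12
OULU	Finland	m9_12	84	84	23	61	12
SKOT1	Denmark	m9_12	115	115	16	99	9
SKOT2	Denmark	m9_12	107	106	36	70	9
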