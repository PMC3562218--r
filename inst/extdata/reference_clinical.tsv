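patient_id	no_n_nl_min	tem_pct_abnormal	same_defect	defect_label	cilia_orientation
1	15	100	TRUE	IDA+NL	Poor
2	0	100	TRUE	ODA	N
3	5.9	100	TRUE	ODA	N
4	5.7	92	TRUE	ODA	N
5	34	100	TRUE	IDA+NL	N
6	4.2	100	TRUE	ODA	N
7	59.8	100	TRUE	ODA	N
8	11.1	100	TRUE	ODA	N
9	6	100	TRUE	ODA	N
10	13	100	TRUE	ODA	N
11	809	7	FALSE	No	N
12	260	1.5	FALSE	No	N
13	219	2	FALSE	No	N
14	194	9	FALSE	No	N
15	661	6	FALSE	No	N
16	183	2	FALSE	No	N
17	100	7	FALSE	No	N
18	639	3	FALSE	No	N
19	282	2	FALSE	No	N
20	784	3	FALSE	No	N
21	264	15	TRUE	CC	N
22	132	4	FALSE	No	N
23	250	0	FALSE	No	N
24	263	3	FALSE	No	N
25	324	0	FALSE	No	N
26	83	2	FALSE	No	N
27	17	6.5	FALSE	Heterogeneous	N
28	15	14	FALSE	Heterogeneous	Poor
29	93	21	TRUE	ODA	N
30	5	30	FALSE	Heterogeneous	N
31	1	0	FALSE	No	N
32	1	10	FALSE	Heterogeneous	Poor
33	262	55	TRUE	ODA+IDA	Poor
34	6.4	22	TRUE	CC	N
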