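patient_id	pct_abnormal_total	pct_virtually_immotile	pct_stiff	pct_circular	dyskinesia_score	weighted_dist_um	weighted_area_um2
1	85	55	30	0	2.40	1.2	3.3
2	80	70	10	0	2.35	0.5	1.3
3	95	90	5	0	2.83	0.0	0.0
4	50	35	15	0	1.45	6.2	17.5
5	55	5	50	0	1.4	5.8	16.0
6	75	30	45	0	2.03	5.2	12.9
7	10	5	5	0	0.25	27.1	87.9
8	100	90	10	0	2.95	0.6	1.8
9	100	100	0	0	3	0.0	0.0
10	100	100	0	0	3	0.0	0.0
11	0	0	0	0	0	53.3	184.6
12	10	0	10	0	0.25	82.8	267.8
13	5	0	5	0	0.15	53.7	148.2
14	5	0	5	0	0.15	77	256.6
15	0	0	0	0	0	76.1	236.2
16	10	0	10	0	0.25	80.9	248.8
17	20	0	20	0	0.5	75.6	251.5
18	20	0	20	0	0.5	34.1	95.8
19	25	0	25	0	0.63	67.7	218.7
20	25	20	5	0	0.73	68.1	199.8
21	20	0	20	0	0.5	39.9	116.8
22	5	0	5	0	0.13	50.3	163.4
23	25	0	25	0	0.63	43.2	119.8
24	0	0	0	0	0	46.0	181.2
25	5	0	5	0	0.13	59.6	160.8
26	0	0	0	0	0	73.3	214.8
27	90	80	10	0	2.65	0.0	0.0
28	60	45	15	0	1.75	9.1	27.3
29	20	0	20	0	0.5	30.3	85.6
30	90	90	0	0	2.7	0.0	0.0
31	70	0	70	0	2.1	29.3	97.9
32	55	5	45	5	1.40	28.6	90.1
33	0	0	0	0	0.0	76.0	242.8
34	60	15	40	5	1.55	5.7	17.8
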