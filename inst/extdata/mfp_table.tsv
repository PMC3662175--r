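id	weight	expression	location	range	signal	category
1	2.15	TTT	7	5	5SS	MFP
2	1.23	TGG	7	5	5SS	MFP
3	3.13	GGG	7	5	5SS	MFP
4	1.00	CTG	7	5	5SS	MFP
5	6.49	TTT	10	17	5SS	MFP
6	2.25	TGG	10	17	5SS	MFP
7	3.42	TCT	10	17	5SS	MFP
8	8.45	GGG	10	17	5SS	MFP
9	4.52	CTG	10	17	5SS	MFP
10	23.76	TTT	25	68	5SS	MFP
11	5.90	TGG	25	68	5SS	MFP
12	9.66	TCT	25	68	5SS	MFP
13	34.39	GGG	25	68	5SS	MFP
14	11.63	CTG	25	68	5SS	MFP
15	17.72	AAA	25	68	5SS	MFP
16	7.11	TTT	91	11	5SS	MFP
17	2.02	TCT	91	11	5SS	MFP
18	4.18	GGG	91	11	5SS	MFP
19	3.23	CTG	91	11	5SS	MFP
20	3.65	AAA	91	11	5SS	MFP
21	7.63	TTT	4	5	3SS	MFP
22	5.08	TCT	5	5	3SS	MFP
23	33.13	TTT	7	17	3SS	MFP
24	11.63	TGT	7	17	3SS	MFP
25	25.46	TCT	7	17	3SS	MFP
25	3.80	CTG	7	17	3SS	MFP
27	3.20	ATT	7	17	3SS	MFP
28	20.08	TTT	22	47	3SS	MFP
29	7.39	TGT	22	47	3SS	MFP
30	12.52	TCT	22	47	3SS	MFP
31	9.78	CTG	22	47	3SS	MFP
32	7.07	ATT	22	47	3SS	MFP
33	17.48	AAA	22	47	3SS	MFP
34	2.11	TTT	67	8	3SS	MFP
35	1.76	TCT	67	8	3SS	MFP
36	2.28	CTG	67	8	3SS	MFP
37	1.89	ATT	67	8	3SS	MFP
38	2.25	AAA	67	8	3SS	MFP
39	1.51	TTT	75	5	3SS	MFP
40	1.27	CTG	75	5	3SS	MFP
41	1.02	ATT	75	5	3SS	MFP
42	1.23	AAA	75	5	3SS	MFP
43	8.31	TTT	76	26	3SS	MFP
44	3.41	ATT	76	26	3SS	MFP
45	9.53	AAA	76	26	3SS	MFP
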