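id	weight	expression	location	range	signal	category
1	5.30	AAG	1	5	5SS	UFP
2	2.01	GAG	1	5	5SS	UFP
3	3.98	GTA	1	5	5SS	UFP
4	2.02	TAA	1	5	5SS	UFP
5	2.32	TGA	1	5	5SS	UFP
6	4.54	AGT	4	5	5SS	UFP
7	3.12	ACA	1	5	3SS	UFP
8	6.26	CAG	1	5	3SS	UFP
9	1.00	CCA	1	5	3SS	UFP
10	1.09	GCA	1	5	3SS	UFP
11	2.69	TAG	1	5	3SS	UFP
12	2.33	TCA	1	5	3SS	UFP
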