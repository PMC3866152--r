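# Top 25 genes by weighted degree centrality in the explicit (GG) and
# citation-mediated (GCG) networks, with the dominant GAD disease category
# and its supporting paper count (blank category -> no GAD record).
network	rank	gene	value	category	paper_count
GG	1	TP53	23090	CANCER	360
GG	2	MDM2	8451	CANCER	126
GG	3	POU5F1	7187	IMMUNE	10
GG	4	SOX2	6278	VISION	5
GG	5	CLOCK	5145	PSYCH	16
GG	6	NANOG	4808	CARDIOVASCULAR	1
GG	7	RAD51	4584	CANCER	68
GG	8	MXI1	3397	IMMUNE	2
GG	9	MYC	3275	CANCER	27
GG	10	DNMT3A	3063	CANCER	7
GG	11	CDC20	2810	CANCER	68
GG	12	PINK1	2569	NEUROLOGICAL	39
GG	13	DMC1	2476	REPRODUCTION	2
GG	14	HRAS	2420	CANCER	25
GG	15	CDKN2A	2393	CANCER	131
GG	16	DNMT3B	2357	CANCER	27
GG	17	E2F1	2340	CANCER	2
GG	18	TP73	2323	CANCER	28
GG	19	TP63	2252	CANCER	11
GG	20	BCL2	2197	CANCER	33
GG	21	BUB1B	2045	CANCER	3
GG	22	PARK2	2041	NEUROLOGICAL	82
GG	23	ATR	2021	CARDIOVASCULAR	2
GG	24	CHEK2	1992	CANCER	105
GG	25	RAD52	1808	CANCER	19
GCG	1	TP53	29859	CANCER	360
GCG	2	MDM2	11413	CANCER	126
GCG	3	RAD51	4991	CANCER	68
GCG	4	PINK1	4974	NEUROLOGICAL	39
GCG	5	TP63	4717	CANCER	11
GCG	6	CLOCK	4536	PSYCH	16
GCG	7	SOX2	4244	VISION	5
GCG	8	MXI1	4099	IMMUNE	2
GCG	9	CDC20	3882	CANCER	2
GCG	10	TP73	3786	CANCER	28
GCG	11	PARK2	3735	NEUROLOGICAL	82
GCG	12	MDM4	3630	CANCER	6
GCG	13	CTCF	3475	METABOLIC	3
GCG	14	MYC	3466	CANCER	27
GCG	15	BCL2	3203	CANCER	33
GCG	16	DISC1	3133	PSYCH	38
GCG	17	NDEL1	3121	PSYCH	3
GCG	18	CDKN2A	3048	CANCER	131
GCG	19	POU5F1	2998	IMMUNE	10
GCG	20	DMC1	2549	REPRODUCTION	2
GCG	21	PLK1	2505	CANCER	6
GCG	22	CTCFL	2463	CANCER	1
GCG	23	BCL2L1	2373	CANCER	7
GCG	24	USP7	2309	CARDIOVASCULAR	2
GCG	25	RAD9A	2306	CANCER	1
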