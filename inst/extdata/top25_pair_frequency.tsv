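# Top 25 gene pairs by co-occurrence frequency in the explicit (GG) and
# citation-mediated (GCG) networks, with curation remarks:
#   Interaction          -> pair reported in the interaction repository
#   Same gene family     -> unreported there, but members of one family
#   Literature-confirmed -> unreported there, interaction confirmed by review
#   No interaction       -> no interaction evidence found
# DIO_2 is normalized to DIO2 at transcription.
network	rank	gene_a	gene_b	freq	remark
GG	1	MDM2	TP53	6684	Interaction
GG	2	POU5F1	SOX2	3116	Interaction
GG	3	NANOG	POU5F1	2805	Interaction
GG	4	NANOG	SOX2	1912	Interaction
GG	5	PARK2	PINK1	1726	Interaction
GG	6	DMC1	RAD51	1671	Interaction
GG	7	HRAS	TP53	1649	Interaction
GG	8	TP53	TP73	1604	Interaction
GG	9	TP53	TP63	1555	Interaction
GG	10	DNMT3A	DNMT3B	1471	Interaction
GG	11	CDC20	MXI1	1392	Interaction
GG	12	RAD51	RAD52	1301	Interaction
GG	13	CDKN2A	TP53	1225	Interaction
GG	14	DNMT3A	DNMT3L	1139	Interaction
GG	15	ARNTL	CLOCK	1069	Interaction
GG	16	SMN1	SMN2	868	Interaction
GG	17	MDM2	MDM4	840	Interaction
GG	18	RAG1	RAG2	816	Interaction
GG	19	MRE11A	RAD50	814	Interaction
GG	20	MXD1	MXI1	763	Same gene family
GG	21	ATR	CHEK2	751	Interaction
GG	22	BCL2	TP53	727	Interaction
GG	23	BUB1	BUB1B	702	Interaction
GG	24	CTCF	H19	676	Literature-confirmed
GG	25	DIO2	LMOD1	669	Same gene family
GCG	1	MDM2	TP53	7264	Interaction
GCG	2	TP53	TP63	2799	Interaction
GCG	3	TP53	TP73	2686	Interaction
GCG	4	PARK2	PINK1	2521	Interaction
GCG	5	CDC20	MXI1	2507	Interaction
GCG	6	CDKN2A	TP53	1963	Interaction
GCG	7	MDM4	TP53	1845	Interaction
GCG	8	DISC1	NDEL1	1778	Interaction
GCG	9	MDM2	MDM4	1553	Interaction
GCG	10	NEDD4	NEDD4L	1461	Same gene family
GCG	11	CTCF	CTCFL	1389	Same gene family
GCG	12	POU5F1	SOX2	1320	Interaction
GCG	13	TP53	USP7	1283	Interaction
GCG	14	BCL2	BCL2L1	1199	Interaction
GCG	15	BCL2	SOD1	1112	Interaction
GCG	16	DMC1	RAD51	1074	Interaction
GCG	17	TP63	TP73	907	Interaction
GCG	18	HRAS	TP53	904	Interaction
GCG	19	ECT2	PLK1	884	Literature-confirmed
GCG	20	DISC1	NDE1	858	Literature-confirmed
GCG	21	NANOG	POU5F1	851	Interaction
GCG	22	ARNTL	CLOCK	850	Interaction
GCG	23	MDM2	USP7	822	Interaction
GCG	24	FXR1	FXR2	815	Interaction
GCG	25	SOX9	WNT4	810	No interaction
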