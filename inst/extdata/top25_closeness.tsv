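# Top 25 genes by closeness centrality in the explicit (GG) and
# citation-mediated (GCG) networks, with the dominant GAD disease category
# and its supporting paper count (blank category -> no GAD record).
# The printed closeness values come from the original network tool's
# average-path-length style output and exceed 1; they are kept verbatim
# for set-level aggregates only. Where the source lists two categories
# for one gene (CHL1), the first is kept.
network	rank	gene	value	category	paper_count
GG	1	MC4R	10.22680412	METABOLIC	95
GG	2	EIF4G1	10.1443299		0
GG	3	TRAF3IP1	9.664948454		0
GG	4	MAP1A	9.664948454	PSYCH	2
GG	5	PIF1	9.412371134		0
GG	6	FEN1	9.412371134	CANCER	5
GG	7	CDKAL1	9.231958763	IMMUNE	13
GG	8	SLC30A8	9.231958763	METABOLIC	88
GG	9	IGF2BP2	9.231958763	METABOLIC	78
GG	10	FTO	9.229381443	METABOLIC	197
GG	11	NPAT	9.146907216		0
GG	12	NDE1	8.677835052	PSYCH	3
GG	13	NDEL1	8.670103093		0
GG	14	DISC1	8.667525773	PSYCH	38
GG	15	CYBB	8.590206186		0
GG	16	OTX1	8.50257732		0
GG	17	CHL1	8.425257732	HEMATOLOGICAL	2
GG	18	DNA2	8.414948454	CHEMDEPENDENCY	1
GG	19	KCNE1	8.270618557	CARDIOVASCULAR	37
GG	20	HHEX	8.244845361	METABOLIC	92
GG	21	MSX2	8.18814433	METABOLIC	5
GG	22	NEUROG1	8.167525773	PSYCH	4
GG	23	MEF2C	8.164948454	METABOLIC	7
GG	24	MYOG	8.164948454	METABOLIC	1
GG	25	ELSPBP1	8.154639175		0
GCG	1	SH2B3	9.095982143	IMMUNE	18
GCG	2	OLIG2	9.095982143	PSYCH	3
GCG	3	BLCAP	9.080357143		0
GCG	4	BMP4	8.631696429	CANCER	7
GCG	5	RPGRIP1L	8.595982143	PSYCH	1
GCG	6	RCC1	8.595982143		0
GCG	7	RAB3IP	8.595982143		0
GCG	8	RAB8A	8.59375		0
GCG	9	CEP290	8.59375		0
GCG	10	ALKBH1	8.495535714		0
GCG	11	KDM5A	8.495535714		0
GCG	12	KDM4A	8.495535714	CARDIOVASCULAR	1
GCG	13	KDM4C	8.495535714		0
GCG	14	JARID2	8.495535714		0
GCG	15	RPH3A	8.457589286		0
GCG	16	RPS6KB1	8.354910714	CANCER	2
GCG	17	NPR1	8.354910714	CARDIOVASCULAR	12
GCG	18	RICTOR	8.354910714	CANCER	1
GCG	19	NPRL2	8.354910714		0
GCG	20	NPR2	8.354910714	CARDIOVASCULAR	2
GCG	21	SPSB1	8.332589286		0
GCG	22	SPSB2	8.332589286		0
GCG	23	SPSB4	8.332589286		0
GCG	24	KDM6A	8.207589286	IMMUNE	1
GCG	25	IRS2	8.178571429	METABOLIC	29
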