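subgroup_id	label	ligand	class	orphan	flags	included
1	CHRM1	acetylcholine	small	0		1
1	CHRM2	acetylcholine	small	0		1
1	CHRM3	acetylcholine	small	0		1
1	CHRM4	acetylcholine	small	0		1
1	CHRM5	acetylcholine	small	0		1
2	DRD1	dopamine	small	0		1
2	DRD2	dopamine	small	0		1
2	DRD3	dopamine	small	0		1
2	DRD4	dopamine	small	0		1
2	DRD5	dopamine	small	0		1
3	P2RY12	nucleotides	small	0	o,S	1
3	P2RY13	nucleotides	small	0	o,S	1
3	P2RY14	nucleotides	small	0	o,S	1
3	GPR87	lysophosphatidic acid	small	0	o,S	1
3	GPR171		NA	1	o,S	1
4	HTR1A	5-hydroxytryptamine	small	0		1
4	HTR1B	5-hydroxytryptamine	small	0		1
4	HTR1D	5-hydroxytryptamine	small	0		1
4	HTR1F	5-hydroxytryptamine	small	0		1
4	HTR1E	5-hydroxytryptamine	small	0		1
4	HTR5A	5-hydroxytryptamine	small	0		1
4	HTR7	5-hydroxytryptamine	small	0		1
5	P2RY1	nucleotides	small	0		1
5	P2RY2	nucleotides	small	0		1
5	P2RY4	nucleotides	small	0		1
5	P2RY6	nucleotides	small	0		1
5	P2RY11	nucleotides	small	0		1
6	MTNR1A	melatonin	small	0	o	1
6	MTNR1B	melatonin	small	0	o	1
6	GPR50		NA	1	o	1
7	ADRA1A	adrenaline	small	0		1
7	ADRA1B	adrenaline	small	0		1
7	ADRB1	adrenaline	small	0		1
7	ADRB2	adrenaline	small	0		1
7	ADRB3	adrenaline	small	0		1
8	HTR2A	5-hydroxytryptamine	small	0		1
8	HTR2B	5-hydroxytryptamine	small	0		1
8	HTR2C	5-hydroxytryptamine	small	0		1
9	HRH1	histamine	small	0		1
9	HRH2	histamine	small	0		1
9	HRH3	histamine	small	0		1
9	HRH4	histamine	small	0		1
10	ADORA1	adenosine	small	0		1
10	ADORA2A	adenosine	small	0		1
10	ADORA2B	adenosine	small	0		1
11	S1PR2	sphingosine 1-phosphate	lipid	0		1
11	S1PR1	sphingosine 1-phosphate	lipid	0		1
11	S1PR3	sphingosine 1-phosphate	lipid	0		1
11	S1PR5	sphingosine 1-phosphate	lipid	0		1
11	LPAR1	lysophosphatidic acid	lipid	0		1
11	LPAR3	lysophosphatidic acid	lipid	0		1
12	GPR3	sphingosine 1-phosphate	lipid	0		1
12	GPR6	sphingosine 1-phosphate	lipid	0		1
12	GPR12	sphingosine 1-phosphate	lipid	0		1
13	FFAR1	free fatty acids	lipid	0		1
13	FFAR2	free fatty acids	lipid	0		1
13	FFAR3	free fatty acids	lipid	0		1
14	PTGDR	prostaglandins	lipid	0		1
14	PTGER1	prostaglandins	lipid	0		1
14	PTGER3	prostaglandins	lipid	0		1
14	PTGER4	prostaglandins	lipid	0		1
14	PTGFR	prostaglandins	lipid	0		1
14	PTGIR	prostaglandins	lipid	0		1
14	TBXA2R	thromboxane	lipid	0		1
15	CYSLTR1	cysteinyl leukotrienes	lipid	0		1
15	CYSLTR2	cysteinyl leukotrienes	lipid	0		1
15	GPR17	cysteinyl leukotrienes	lipid	0		1
13b	FFAR1	free fatty acids	lipid	0		0
13b	FFAR2	free fatty acids	lipid	0		0
13b	FFAR3	free fatty acids	lipid	0		0
13b	GPR42	free fatty acids	lipid	0		0
16	LPAR4	lysophosphatidic acid	lipid	0	o	1
16	LPAR6	lysophosphatidic acid	lipid	0	o	1
16	GPR174		NA	1	o	1
16	P2RY10	sphingosine 1-phosphate	lipid	0	o	1
16	PTAFR	platelet activating factor	lipid	0	o	1
17	RRH	retinoids	lipid	0		1
17	OPN3	retinoids	lipid	0		1
17	OPN4	retinoids	lipid	0		1
17	OPN5	retinoids	lipid	0		1
17	RGR	retinoids	lipid	0		1
18	OPN1MW	retinoids	lipid	0		1
18	OPN1LW	retinoids	lipid	0		1
18	RHO	retinoids	lipid	0		1
18	OPN1SW	retinoids	lipid	0		1
19	GPR81	hydroxylated fatty acids	lipid	0		1
19	GPR109B	hydroxylated fatty acids	lipid	0		1
19	GPR109A	hydroxylated fatty acids	lipid	0		1
20	TACR1	tachykinin neuropeptides	peptide	0		1
20	TACR2	tachykinin neuropeptides	peptide	0		1
20	TACR3	tachykinin neuropeptides	peptide	0		1
21	TSHR	glycoprotein hormones	peptide	0		1
21	LHCGR	glycoprotein hormones	peptide	0		1
21	FSHR	glycoprotein hormones	peptide	0		1
22	F2R	unmasked N-terminus	peptide	0		1
22	F2RL1	unmasked N-terminus	peptide	0		1
22	F2RL2	unmasked N-terminus	peptide	0		1
22	F2RL3	unmasked N-terminus	peptide	0		1
23	GPR83		NA	1	o	1
23	NPY1R	neuropeptide Y	peptide	0	o	1
23	NPY2R	neuropeptide Y	peptide	0	o	1
23	PPYR1	peptide YY	peptide	0	o	1
23	NPY5R	neuropeptide Y	peptide	0	o	1
24	C3AR1	anaphylatoxins	peptide	0		1
24	C5AR1	anaphylatoxins	peptide	0		1
24	GPR77	anaphylatoxins	peptide	0		1
25	EDNRA	endothelins	peptide	0	o	1
25	EDNRB	endothelins	peptide	0	o	1
25	GPR37		NA	1	o	1
25	GPR37L1		NA	1	o	1
26	LGR5		NA	1		1
26	LGR6		NA	1		1
26	RXFP1	relaxin	peptide	0		1
26	RXFP2	relaxin	peptide	0		1
27	GALR1	galanin	peptide	0	N	1
27	GALR2	galanin	peptide	0	N	1
27	GALR3	galanin	peptide	0	N	1
28	OPRL1	opioid peptides	peptide	0	N	1
28	OPRM1	opioid peptides	peptide	0	N	1
28	OPRD1	opioid peptides	peptide	0	N	1
28	OPRK1	opioid peptides	peptide	0	N	1
29	SSTR2	somatostatins	peptide	0		1
29	SSTR3	somatostatins	peptide	0		1
29	SSTR5	somatostatins	peptide	0		1
30	GRPR	bombesin-related peptides	peptide	0		1
30	NMBR	bombesin-related peptides	peptide	0		1
30	BRS3	bombesin-related peptides	peptide	0		1
31	MC3R	melanocortins	peptide	0	N	1
31	MC4R	melanocortins	peptide	0	N	1
31	MC5R	melanocortins	peptide	0	N	1
32	AVPR1A	vasopressin	peptide	0	N	1
32	AVPR1B	vasopressin	peptide	0	N	1
32	AVPR2	vasopressin	peptide	0	N	1
33	CXCR1	chemokines	peptide	0		1
33	CXCR2	chemokines	peptide	0		1
33	CXCR3	chemokines	peptide	0		1
33	CXCR4	chemokines	peptide	0		1
33	CXCR5	chemokines	peptide	0		1
33	CXCR6	chemokines	peptide	0		1
33	CCR6	chemokines	peptide	0		1
33	CCR7	chemokines	peptide	0		1
33	CCR9	chemokines	peptide	0		1
33	CCR10	chemokines	peptide	0		1
34	APLNR	apelin	peptide	0		1
34	AGTR1	angiotensin	peptide	0		1
34	RL3R1	relaxin	peptide	0		1
34	RXFP4	relaxin	peptide	0		1
35	NTSR1	neurotensin	peptide	0		1
35	NTSR2	neurotensin	peptide	0		1
35	GPR39	obestatin	peptide	0		1
36	CCR1	chemokines	peptide	0	S	1
36	CCR2	chemokines	peptide	0	S	1
36	CCR3	chemokines	peptide	0	S	1
36	CCR4	chemokines	peptide	0	S	1
36	CCR5	chemokines	peptide	0	S	1
36	CCR8	chemokines	peptide	0	S	1
36	CCRL2	chemokines	peptide	0	S	1
36	CX3CR1	chemokines	peptide	0	S	1
36	CCBP2	chemokines	peptide	0	S	1
37	FPR1	N-formyl-methionyl peptides	peptide	0		1
37	FPR2	N-formyl-methionyl peptides	peptide	0		1
37	FPR3	N-formyl-methionyl peptides	peptide	0		1
38	MRGPRX1	enkephalins	peptide	0	o	1
38	MRGPRX2	cortistatins	peptide	0	o	1
38	MRGPRX3		NA	1	o	1
38	MRGPRX4		NA	1	o	1
39	GPR101		NA	1	o	1
39	GPR161		NA	1	o	1
39	GPR135		NA	1	o	1
39	GPR63	sphingosine 1-phosphate	lipid	0	o	1
39	GPR45		NA	1	o	1
40	GPR4	protons	ion	0	N	1
40	GPR65	glycosphingolipids	lipid	0	N	1
40	GPR68	protons	ion	0	N	1
41	MAS1	angiotensin	peptide	0	o	1
41	MAS1L		NA	1	o	1
41	MRGPRD	beta-alanine	small	0	o	1
41	MRGPRF		NA	1	o	1
42	TAAR1	trace amines	small	0	o,S	1
42	TAAR5		NA	1	o,S	1
42	TAAR6		NA	1	o,S	1
42	TAAR8		NA	1	o,S	1
42	TAAR9		NA	1	o,S	1
43	C3AR1	anaphylatoxins	peptide	0		1
43	C5AR1	anaphylatoxins	peptide	0		1
43	GPR77	anaphylatoxins	peptide	0		1
43	CMKLR1	chemokines	peptide	0		1
43	FPR1	N-formyl-methionyl peptides	peptide	0		1
43	FPR2	N-formyl-methionyl peptides	peptide	0		1
43	FPR3	N-formyl-methionyl peptides	peptide	0		1
43	GPR1	chemerin	peptide	0		1
43	GPR32	resolvins	lipid	0		1
43	GPR44	prostanoids	lipid	0		1
44	MAS1	angiotensin	peptide	0	o	1
44	MAS1L		NA	1	o	1
44	MRGPRD	beta-alanine	small	0	o	1
44	MRGPRF		NA	1	o	1
44	MRGPRX1	enkephalins	peptide	0	o	1
44	MRGPRX2	cortistatins	peptide	0	o	1
44	MRGPRX3		NA	1	o	1
44	MRGPRX4		NA	1	o	1
45	GPR27		NA	1	o	1
45	GPR85		NA	1	o	1
45	GPR173		NA	1	o	1
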