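Neuron	cortical neuron markers (curated from literature)	SNAP25	RBFOX3	SYT1	NRGN	CCK	MAP1B	STMN2	THY1	NEFL	GRIN1	GABRA1	SLC17A7	GAD1	CAMK2A	SYN1	DLG4	NRXN1	CELF4	MAP2	BEX3
Astrocyte	protoplasmic astrocyte markers (curated from literature)	AQP4	GJA1	SLC1A3	GLUL	FGFR3	ALDH1L1	SLC4A4	GPC5	MLC1	SOX9	NTSR2	ATP1A2	BMPR1B	CLU	CST3	TTYH1	GJB6	SLC14A1	NDRG2	MFGE8
Oligodendrocyte	myelinating oligodendrocyte markers (curated from literature)	PLP1	MBP	MOBP	MOG	MAG	CNP	CLDN11	OPALIN	MYRF	UGT8	ASPA	KLK6	ERMN	TF	CA2	SOX10	ST18	FOLH1	GJB1	CD82
OPC	oligodendrocyte precursor markers (curated from literature)	PDGFRA	CSPG4	OLIG1	OLIG2	SOX10	VCAN	GPR17	LHFPL3	DSCAM	PCDH15	PTPRZ1	BCAN	NEU4	CA10	SMOC1	COL9A1	S100B	SSH3	MEGF11	XYLT1
Microglia	microglia markers (curated from literature)	C1QA	C1QB	C1QC	CSF1R	P2RY12	CX3CR1	AIF1	TMEM119	ITGAM	TYROBP	CTSS	HLA-DRA	HLA-B	FCGR3A	DOCK8	APBB1IP	IKZF1	RUNX1	SPI1	MRC1
Endothelial	brain endothelial markers (curated from literature)	CLDN5	FLT1	PECAM1	VWF	A2M	ABCB1	SLC2A1	ITM2A	RGS5	PDGFRB	NOTCH3	EPAS1	TEK	ESAM	ICAM2	PTPRB	ERG	SOX17	CD34	ENG
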