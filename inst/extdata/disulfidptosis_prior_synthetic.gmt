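DISULFIDPTOSIS_SYNTHETIC	Synthetic stand-in for the FerrDb disulfidptosis prior set (84 curated-style human gene symbols; not the database export)	SLC7A11	SLC3A2	RPN1	NCKAP1	NUBPL	NDUFA11	LRPPRC	OXSM	NDUFS1	GYS1	G6PD	PGD	TKT	TALDO1	RPIA	SLC2A1	SLC2A3	PFKL	PFKM	ALDOA	GAPDH	PGK1	ENO1	PKM	LDHA	ACTB	ACTG1	ACTN4	FLNA	FLNB	MYH9	MYH10	MYH14	MYL6	TLN1	CAPZB	DSTN	CD2AP	INF2	WASF1	WASF2	WASF3	ABI1	ABI2	CYFIP1	CYFIP2	BRK1	RAC1	NCKAP1L	ACTR2	ACTR3	ARPC1B	ARPC2	ARPC3	ARPC4	ARPC5	CTTN	CFL1	CFL2	PFN1	TPM1	TPM3	TPM4	MYL12A	MYL12B	VCL	PXN	ZYX	TJP1	CDH2	ITGB1	ITGA3	FERMT2	PARVA	GCLC	GCLM	GSS	GPX1	TXN	TXNRD1	PRDX1	NFE2L2	KEAP1	SLC1A5
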