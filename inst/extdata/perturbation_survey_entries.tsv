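mirna	dataset	cancer_context	direction	corr_sign	gene	perturbation
mir-335	GSE68742	SARC	down	negative	CFLAR	overexpression
mir-335	GSE68742	SARC	down	negative	FIGN	overexpression
mir-335	GSE68742	SARC	down	negative	MSRB3	overexpression
mir-335	GSE68742	SARC	down	negative	SOD3	overexpression
mir-335	GSE68742	SARC	down	negative	RGS2	overexpression
mir-335	GSE68742	SARC	down	negative	SGK1	overexpression
mir-335	GSE68742	SARC	down	negative	PMP22	overexpression
mir-335	GSE68742	SARC	down	positive	CCDC3	overexpression
mir-335	GSE68742	SARC	down	positive	LDB2	overexpression
mir-335	GSE68742	SARC	down	positive	DZIP1	overexpression
mir-335	GSE68742	SARC	down	positive	KLF2	overexpression
mir-335	GSE68742	SARC	down	positive	CXCL12	overexpression
mir-335	GSE68742	SARC	down	positive	NTRK3	overexpression
mir-335	GSE68742	SARC	down	positive	PABPC5	overexpression
mir-335	GSE68742	SARC	down	positive	RBMS3	overexpression
mir-335	GSE68742	SARC	down	positive	RCBTB2	overexpression
mir-335	GSE68742	SARC	down	positive	RUNX1T1	overexpression
mir-335	GSE68742	SARC	up	negative	A2M	overexpression
mir-335	GSE68742	SARC	up	negative	ACTA2	overexpression
mir-335	GSE68742	SARC	up	negative	DUSP3	overexpression
mir-335	GSE68742	SARC	up	negative	TNFSF10	overexpression
mir-335	GSE68742	SARC	up	negative	SGCB	overexpression
mir-335	GSE68742	SARC	up	negative	SPARCL1	overexpression
mir-335	GSE68742	SARC	up	negative	SSFA2	overexpression
mir-335	GSE68742	SARC	up	negative	FAS	overexpression
mir-335	GSE68742	SARC	up	positive	EGR2	overexpression
mir-335	GSE68742	SARC	up	positive	JDP2	overexpression
mir-335	GSE68742	SARC	up	positive	PRICKLE1	overexpression
mir-335	GSE68742	SARC	up	positive	LOC728392	overexpression
mir-335	GSE68742	SARC	up	positive	MATN2	overexpression
mir-335	GSE68742	SARC	up	positive	LMO2	overexpression
mir-335	GSE9586	LUAD	down	negative	CD247	overexpression
mir-335	GSE9586	LUAD	down	negative	DPYD	overexpression
mir-335	GSE9586	LUAD	down	negative	F3	overexpression
mir-335	GSE9586	LUAD	down	negative	LHFP	overexpression
mir-335	GSE9586	LUAD	down	negative	PTX3	overexpression
mir-335	GSE9586	LUAD	down	negative	MNDA	overexpression
mir-335	GSE9586	LUAD	down	negative	MT1E	overexpression
mir-335	GSE9586	LUAD	down	negative	MYL9	overexpression
mir-335	GSE9586	LUAD	down	negative	SCD5	overexpression
mir-335	GSE9586	LUAD	down	negative	SLFN11	overexpression
mir-335	GSE9586	LUAD	down	positive	OSR2	overexpression
mir-335	GSE9586	LUAD	up	negative	ADAM23	overexpression
mir-335	GSE9586	LUAD	up	negative	CALD1	overexpression
mir-335	GSE9586	LUAD	up	negative	CALHM2	overexpression
mir-335	GSE9586	LUAD	up	negative	CTTNBP2NL	overexpression
mir-335	GSE9586	LUAD	up	negative	DIXDC1	overexpression
mir-335	GSE9586	LUAD	up	negative	DUSP3	overexpression
mir-335	GSE9586	LUAD	up	negative	FBXL7	overexpression
mir-335	GSE9586	LUAD	up	negative	GCC2	overexpression
mir-335	GSE9586	LUAD	up	negative	GLI3	overexpression
mir-335	GSE9586	LUAD	up	negative	HVCN1	overexpression
mir-335	GSE9586	LUAD	up	negative	JAK1	overexpression
mir-335	GSE9586	LUAD	up	negative	MCTP1	overexpression
mir-335	GSE9586	LUAD	up	negative	SGCB	overexpression
mir-335	GSE9586	LUAD	up	negative	RHOJ	overexpression
mir-335	GSE9586	LUAD	up	negative	PCDHGA9	overexpression
mir-192	GSE62951	LIHC	down	negative	E2F7	overexpression
mir-192	GSE62951	LIHC	down	negative	KIF2C	overexpression
mir-192	GSE62951	LIHC	down	negative	MTBP	overexpression
mir-192	GSE62951	LIHC	down	negative	NCS1	overexpression
mir-192	GSE62951	LIHC	down	negative	RAD54L	overexpression
mir-192	GSE62951	LIHC	up	positive	KIF4A	overexpression
mir-192	GSE69990	OV	down	negative	SERTAD2	overexpression
mir-192	GSE69990	OV	down	positive	BIRC5	overexpression
mir-192	GSE69990	OV	down	positive	EZH2	overexpression
mir-192	GSE69990	OV	down	positive	PLK1	overexpression
mir-26b	GSE12091	CESC	down	positive	C1S	overexpression
mir-193b	GSE83690	SARC	down	positive	C9orf140	overexpression
mir-193b	GSE83690	SARC	down	positive	CCNB2	overexpression
mir-193b	GSE83690	SARC	down	positive	CENPA	overexpression
mir-193b	GSE83690	SARC	down	positive	KIF23	overexpression
mir-193b	GSE83690	SARC	down	positive	KIF2C	overexpression
mir-193b	GSE83690	SARC	down	positive	NUSAP1	overexpression
mir-193b	GSE83690	SARC	down	positive	TROAP	overexpression
mir-193b	GSE25215	PAAD	up	positive	CCNB2	overexpression
mir-193b	GSE25215	PAAD	up	positive	CDC25C	overexpression
mir-193b	GSE25215	PAAD	up	positive	CENPO	overexpression
mir-193b	GSE25215	PAAD	up	positive	KIF23	overexpression
mir-193b	GSE25215	PAAD	up	positive	KIF2C	overexpression
mir-193b	GSE25215	PAAD	up	positive	PTTG1	overexpression
mir-193b	GSE25215	PAAD	up	positive	TROAP	overexpression
mir-193b	GSE25215	PAAD	up	positive	TTK	overexpression
mir-193b	GSE18510	SKCM	up	positive	BIRC5	overexpression
mir-193b	GSE18510	SKCM	up	positive	KIF2C	overexpression
mir-21	GSE136665	COAD	up	negative	ACADSB	overexpression
mir-21	GSE136665	COAD	up	negative	NAP1L5	overexpression
mir-21	GSE136665	COAD	up	positive	AKAP11	overexpression
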