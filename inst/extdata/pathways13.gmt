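ribosome	cytosolic ribosomal proteins (representative subset)	RPL3	RPL4	RPL5	RPL6	RPL7	RPL11	RPL13	RPL23	RPS3	RPS6	RPS8	RPS11	RPS14	RPS19	RPSA
VEGF	VEGF signaling pathway (representative subset)	VEGFA	VEGFB	VEGFC	FLT1	KDR	FLT4	NRP1	NRP2	PIK3CA	PLCG1	PTGS2	SHC2	SPHK1	HSPB1
cell cycle	cell cycle (representative subset)	CCND1	CCNE1	CCNA2	CCNB1	CDK1	CDK2	CDK4	CDK6	CDKN1A	CDKN1B	CDC20	CDC25A	E2F1	RB1	TP53	MCM2	MYBL2
ERBB2	ERBB signaling pathway (representative subset)	ERBB2	ERBB3	ERBB4	EGFR	NRG1	GRB2	SOS1	SHC1	PIK3R1	AKT1	MAPK1	MAPK3	STAT5A	MYC
PDGFRB	PDGF receptor beta signaling (representative subset)	PDGFRB	PDGFB	PDGFA	PDGFRA	GRB2	SRC	STAT3	PLCG1	RASA1	CRK	PIK3CA	SHC1
p53 signaling	p53 signaling pathway (representative subset)	TP53	MDM2	MDM4	CDKN1A	GADD45A	BAX	BBC3	PMAIP1	SFN	RRM2B	SESN1	SESN2	TP53I3
apoptosis	apoptosis (representative subset)	BCL2	BCL2L1	BAX	BAK1	CASP3	CASP8	CASP9	APAF1	CYCS	FAS	FASLG	BID	XIAP	DIABLO
Wnt	Wnt signaling pathway (representative subset)	WNT1	WNT3A	WNT5A	CTNNB1	APC	AXIN1	GSK3B	LRP5	LRP6	TCF7	LEF1	DVL1	FZD1	MYC	CCND1
MAPK	MAPK signaling pathway (representative subset)	KRAS	HRAS	NRAS	RAF1	BRAF	MAP2K1	MAP2K2	MAPK1	MAPK3	MAPK8	MAPK14	DUSP1	FOS	JUN	ELK1
PI3K-Akt	PI3K-Akt signaling pathway (representative subset)	PIK3CA	PIK3CB	PIK3R1	AKT1	AKT2	AKT3	PTEN	MTOR	RPS6KB1	FOXO3	GSK3B	TSC1	TSC2	PDK1
JAK-STAT	JAK-STAT signaling pathway (representative subset)	JAK1	JAK2	JAK3	TYK2	STAT1	STAT2	STAT3	STAT5A	STAT5B	SOCS1	SOCS3	IL6	IL6R	IFNGR1
TGF-beta	TGF-beta signaling pathway (representative subset)	TGFB1	TGFB2	TGFB3	TGFBR1	TGFBR2	SMAD2	SMAD3	SMAD4	SMAD7	BMP2	BMP4	BMPR1A	ACVR1	ID1
Notch	Notch signaling pathway (representative subset)	NOTCH1	NOTCH2	NOTCH3	NOTCH4	JAG1	JAG2	DLL1	DLL3	DLL4	HES1	HEY1	RBPJ	ADAM17	PSEN1
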