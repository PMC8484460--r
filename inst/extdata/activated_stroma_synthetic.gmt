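ACTIVATED_STROMA_SYNTHETIC	curated activated-stroma / TGF-beta marker stand-in; replace with a published stromal signature for real cohorts	SPARC	COL1A1	COL1A2	COL3A1	COL5A1	COL5A2	COL6A3	COL10A1	COL11A1	POSTN	FN1	FAP	THBS2	ACTA2	TAGLN	PDGFRA	PDGFRB	ZEB1	VIM	FBN1	SULF1	LUM	DCN	VCAN	INHBA	THY1	MMP2	MMP11	TIMP3	SFRP2	SFRP4	CDH11	GREM1	COMP	BGN	TGFB1	TGFB3	TNC	SPON1	EDNRA	LGALS1	CCL2
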