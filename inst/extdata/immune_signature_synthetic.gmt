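IMMUNE_SIGNATURE_SYNTHETIC	curated immune-infiltration marker stand-in; replace with a published immune signature for real cohorts	CD8A	CD8B	CD3D	CD3E	CD3G	CD2	CD247	CD4	GZMA	GZMB	GZMH	GZMK	PRF1	GNLY	NKG7	KLRD1	KLRK1	FASLG	CCL5	CXCL9	CXCL10	CXCL11	CXCL13	CCL19	CCL21	CCR7	SELL	IL7R	IFNG	IDO1	STAT1	TAP1	TAP2	B2M	HLA-A	HLA-B	HLA-C	HLA-DRA	HLA-DRB1	CIITA	CD19	MS4A1	CD79A	CD79B	IGHM	PDCD1	CD274	CTLA4	LAG3	TIGIT	HAVCR2	BTLA	FOXP3	IL2RB	TBX21	EOMES	CD27	CD28	ICOS	TNFRSF9	CD40LG	ZAP70	LCK	ITK	PTPRC
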