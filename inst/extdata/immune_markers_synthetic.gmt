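B_cells	synthetic canonical markers	CD19	MS4A1	CD79A	CD79B	BLK	TNFRSF13B	BANK1
Plasma_cells	synthetic canonical markers	SDC1	MZB1	XBP1	JCHAIN	PRDM1	DERL3
T_cells_CD8	synthetic canonical markers	CD8A	CD8B	GZMK	GZMA	PRF1	NKG7	CD3D
T_cells_CD4	synthetic canonical markers	CD4	CD3E	CD3G	IL7R	CD28	TRAT1
T_regulatory_cells	synthetic canonical markers	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18
NK_cells	synthetic canonical markers	NCR1	KLRD1	KLRK1	GNLY	KIR2DL3	FCGR3A
Macrophages	synthetic canonical markers	CD68	CD163	MSR1	MRC1	CSF1R	SIRPA	ITGAM
Dendritic_cells	synthetic canonical markers	ITGAX	CD1C	CLEC9A	BATF3	FLT3	IRF8
Neutrophils	synthetic canonical markers	FCGR3B	CSF3R	S100A8	S100A9	CXCR2	FPR1
Fibroblasts	synthetic canonical markers	COL1A1	COL1A2	COL3A1	PDGFRB	FAP	THY1	DCN
Endothelial_cells	synthetic canonical markers	PECAM1	VWF	CDH5	CLDN5	FLT1	ENG
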