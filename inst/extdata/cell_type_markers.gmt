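T/NK	major lineage markers	CD3D	CD3E	CD3G	NKG7
Plasma	major lineage markers	JCHAIN	IGKC	IGHG1
B	major lineage markers	CD79A	MS4A1	CD19
Myeloid	major lineage markers	LYZ	CD14	SPP1
CAF	major lineage markers	DCN	LUM	COL1A1
Epithelial	major lineage markers	EPCAM	KRT8	CAPS
Mast	major lineage markers	KIT	CPA3	MS4A2
Endothelial	major lineage markers	VWF	PECAM1	CALCRL
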