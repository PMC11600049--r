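pair_name,ligand,receptor
MIF_CD74_CD44,MIF,CD74+CD44
MIF_CD74_CXCR4,MIF,CD74+CXCR4
SPP1_CD44,SPP1,CD44
CXCL9_CXCR3,CXCL9,CXCR3
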