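chr2	0	50000000	p11	gneg
chr2	50000000	120000000	q11	gneg
chr5	0	50000000	p11	gneg
chr5	50000000	120000000	q11	gneg
chr7	0	50000000	p11	gneg
chr7	50000000	120000000	q11	gneg
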