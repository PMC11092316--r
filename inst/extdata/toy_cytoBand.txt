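chr1	0	4000000	p12	gneg
chr1	4000000	7000000	p11	acen
chr1	7000000	16000000	q11	gpos50
chr2	0	3000000	p11	acen
chr2	3000000	9000000	q11	gneg
chr2	9000000	12000000	q12	gpos50
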