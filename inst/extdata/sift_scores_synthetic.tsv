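locus_id	pos	score
LOC_A	1054	0
LOC_A	1310	0.32
LOC_B	2205	0.05
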