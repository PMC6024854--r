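##gff-version 3
chr1	test	gene	1001	1600	.	+	.	ID=LOC_A
chr1	test	mRNA	1001	1600	.	+	.	ID=LOC_A.1;Parent=LOC_A
chr1	test	five_prime_UTR	1001	1050	.	+	.	Parent=LOC_A.1
chr1	test	CDS	1051	1200	.	+	0	Parent=LOC_A.1
chr1	test	CDS	1301	1450	.	+	0	Parent=LOC_A.1
chr1	test	three_prime_UTR	1451	1600	.	+	.	Parent=LOC_A.1
chr1	test	gene	2001	2500	.	-	.	ID=LOC_B
chr1	test	mRNA	2001	2500	.	-	.	ID=LOC_B.1;Parent=LOC_B
chr1	test	three_prime_UTR	2001	2100	.	-	.	Parent=LOC_B.1
chr1	test	CDS	2101	2400	.	-	0	Parent=LOC_B.1
chr1	test	five_prime_UTR	2401	2500	.	-	.	Parent=LOC_B.1
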