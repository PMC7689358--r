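##fileformat=VCFv4.2
##source=hand-written toy fixture
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3
1	1000000	snp_1	A	B	.	PASS	.	GT	0/0	0/1	1/1
1	2000000	snp_2	A	B	.	PASS	.	GT	0/1	./.	1|1
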