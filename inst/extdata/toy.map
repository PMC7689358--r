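1	snp_1	0.01	1000000
1	snp_2	0.02	2000000
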