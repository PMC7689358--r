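FID IID PAT MAT SEX PHENOTYPE snp_1_A snp_2_A
f1 s1 0 0 0 -9 0 1
f2 s2 0 0 0 -9 2 0
f3 s3 0 0 0 -9 1 2
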