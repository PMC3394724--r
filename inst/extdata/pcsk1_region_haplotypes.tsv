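haplotype	block1	block2	freq_lean	freq_fat
1	AAGGAAGGACGA	AGAGGGAAGAAAAG	0.683	0
2	GGAAGCAACAAG	GAGAAAGGAGGGGA	0.017	0.750
3	GGAAGCAACAAG	AGAGGGAAGAAAAG	0.193	0.196
4	AAGAAAGGACGA	AGAGGGAAGAAAAG	0.063	0
5	AAGAGAAACCAG	GAAGAAAGAGGAAG	0.043	0
6	AAGAGAAGACGA	GAAGAAGGAGGGGA	0	0.052
7	GGAAGCAACAAG	GAAGAAGGAGGGGA	0	0.0002
8	GGGAGAAGACGA	GAAGAAGGAGGGGA	0	0.0002
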