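quantity	value
n_chip_snps	57636
n_snps_after_qc	45578
n_snps_with_chrom	45005
n_significant_snps	569
n_significant_both_traits	342
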