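genotype	pct_x_ndj	pct_4_ndj	adjusted_total
control	0.64	0.16	1878
mau	0.19	0.00	1043
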