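cohort	outcome	or	ci_low	ci_high	n_snps
non-FinnGen	NAFLD	1.99	1.27	3.13	1
FinnGen	NAFLD	1.51	0.84	2.72	1
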