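rsid	effect_allele	other_allele	eaf	beta	se	pvalue
rs2228145	C	A	0.38	-0.07	0.015	4.50e-06
rs12048091	A	G	0.82	-0.09	0.021	1.30e-05
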