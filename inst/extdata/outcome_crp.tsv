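rsid	effect_allele	other_allele	eaf	beta	se	pvalue
rs2228145	C	A	0.38	-0.09	0.002	1.00e-200
rs12048091	A	G	0.82	-0.06	0.003	4.36e-65
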