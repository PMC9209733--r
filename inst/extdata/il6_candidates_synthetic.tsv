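SNP	A1	A2	EAF	BETA	SE	P
rs2228145	C	A	0.38	0.17	0.012	3.34e-45
rs12048091	A	G	0.82	0.09	0.016	3.95e-08
rs10752641	A	T	0.30	0.08	0.014	1.10e-08
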