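rsid_a	rsid_b	r2
rs2228145	rs12048091	0.11
rs2228145	rs10752641	0.05
rs12048091	rs10752641	0.02
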