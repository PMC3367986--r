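og_id	reference_genes	n_reference	n_target
OG5_139532	AT1G77080,AT5G10140,AT5G65050,AT5G65060,AT5G65070,AT5G65080	6	1
OG5_189849	AT1G50680,AT1G51120	2	1
OG5_190004	AT2G17770,AT4G35900	2	1
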