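og_id	reference_genes	n_reference	n_target
OG5_146511	AT1G09530	1	7
OG5_150317	AT3G47500,AT5G39660	2	16
OG5_153332	AT2G41070,AT3G56850	2	15
OG5_170666	AT4G36920	1	7
OG5_177438	AT2G22540	1	8
OG5_190319	AT3G54340	1	8
OG5_211687	AT5G60910	1	7
OG5_212406	AT3G18990	1	14
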