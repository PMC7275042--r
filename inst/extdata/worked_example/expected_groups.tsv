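group_id	anchor	members	n_peptides	spectral_count	bin
1	P251_1	P251_1;P252_1	3	13	microbiome
2	P251_2	P251_2	1	3	microbiome
3	P351_1	P351_1;P351_2	2	8	microbiome
4	P451_1	P451_1	2	4	microbiome
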