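taxid	rank	name	tsm_count	peptide_count	specific_peptide_count	specific_tsm_count
2	superkingdom	Bacteria	24	6	6	24
3	superkingdom	Eukaryota	4	2	2	4
21	phylum	Proteobacteria	24	6	6	24
41	phylum	Ascomycota	4	2	2	4
22	class	Gammaproteobacteria	24	6	6	24
42	class	Saccharomycetes	4	2	2	4
23	order	Enterobacterales	16	4	4	16
33	order	Pseudomonadales	8	2	2	8
43	order	Saccharomycetales	4	2	2	4
24	family	Enterobacteriaceae	16	4	4	16
34	family	Pseudomonadaceae	8	2	2	8
44	family	Saccharomycetaceae	4	2	2	4
25	genus	Escherichia	16	4	4	16
35	genus	Pseudomonas	8	2	2	8
45	genus	Saccharomyces	4	2	2	4
251	species	Escherichia_coli	13	3	2	9
252	species	Escherichia_fergusonii	7	2	1	3
351	species	Pseudomonas_fluvialis	8	2	2	8
451	species	Saccharomyces_cerevisiae	4	2	2	4
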