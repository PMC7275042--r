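taxid	name	specific_tsm_count	share
25	Escherichia	16	0.571428571428571
35	Pseudomonas	8	0.285714285714286
45	Saccharomyces	4	0.142857142857143
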