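taxid	name	n_specific_peptides	source
25	Escherichia	4	target
# fdr=0 target=1 decoy=0
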