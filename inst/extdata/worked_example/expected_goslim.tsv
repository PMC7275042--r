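slim_id	name	namespace	spectral_count
GO:0008152	metabolic process	biological_process	20
GO:0006950	response to stress	biological_process	12
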