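nodule_id	gene	class	detail
N002	BRAF	SNV	p.Val600Glu
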