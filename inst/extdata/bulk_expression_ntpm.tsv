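dataset	gene	small	large
HPA	APOBEC1	26	1.1
HPA	APOBEC3A	0.8	1.5
HPA	APOBEC3B	4.3	12.1
GTEx	APOBEC1	11.9	1.1
GTEx	APOBEC3A	0.8	1.4
GTEx	APOBEC3B	2.1	6
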