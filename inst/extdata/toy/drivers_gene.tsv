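gene	tag	cancer_type
G1	tsg	PAN
G1	tsg	TOY
G2	oncogene	PAN
G2	oncogene	TOY
G3	tsg	PAN
G3	possible oncogene	PAN
G5	possible oncogene	TOY
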