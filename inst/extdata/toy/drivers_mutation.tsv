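gene	pos	ref	alt	label	evidence_score
G1	100	C	T	TSG	20
G1	200	G	A	OG	16
G2	50	A	G	OG	10
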