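sample	gene	alteration_kind	label	strategy
S1	G1	MUTATION	TSG	gene_pan
S1	G2	CNV	OG	gene_pan
S1	G4	MUTATION	NEUTRAL	gene_pan
S1	G5	MUTATION	UNLABELED	gene_pan
S2	G1	MUTATION	TSG	gene_pan
S2	G2	MUTATION	OG	gene_pan
S2	G3	MUTATION	UNLABELED	gene_pan
S2	G4	CNV	NEUTRAL	gene_pan
S3	G1	BOTH	TSG	gene_pan
S3	G4	MUTATION	NEUTRAL	gene_pan
S3	G5	CNV	UNLABELED	gene_pan
S3	G6	MUTATION	UNLABELED	gene_pan
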