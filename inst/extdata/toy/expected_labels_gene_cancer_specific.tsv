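sample	gene	alteration_kind	label	strategy
S1	G1	MUTATION	TSG	gene_cancer_specific
S1	G2	CNV	OG	gene_cancer_specific
S1	G4	MUTATION	NEUTRAL	gene_cancer_specific
S1	G5	MUTATION	OG	gene_cancer_specific
S2	G1	MUTATION	TSG	gene_cancer_specific
S2	G2	MUTATION	OG	gene_cancer_specific
S2	G3	MUTATION	UNLABELED	gene_cancer_specific
S2	G4	CNV	NEUTRAL	gene_cancer_specific
S3	G1	BOTH	TSG	gene_cancer_specific
S3	G4	MUTATION	NEUTRAL	gene_cancer_specific
S3	G5	CNV	OG	gene_cancer_specific
S3	G6	MUTATION	UNLABELED	gene_cancer_specific
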