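sample	gene	alteration_kind	label	strategy
S1	G1	MUTATION	DRIVER	mutation_exact_binary
S1	G4	MUTATION	NEUTRAL	mutation_exact_binary
S1	G5	MUTATION	UNLABELED	mutation_exact_binary
S2	G1	MUTATION	UNLABELED	mutation_exact_binary
S2	G2	MUTATION	UNLABELED	mutation_exact_binary
S2	G3	MUTATION	UNLABELED	mutation_exact_binary
S3	G1	MUTATION	DRIVER	mutation_exact_binary
S3	G4	MUTATION	NEUTRAL	mutation_exact_binary
S3	G6	MUTATION	UNLABELED	mutation_exact_binary
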