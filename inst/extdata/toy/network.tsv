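gene_a	gene_b	experimental_score	database_score
G1	G2	800	0
G1	G3	0	750
G2	G3	700	700
G4	G5	900	100
G5	G5	999	999
G2	G1	0	800
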