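gene	S1	S2	S3
G1	0	0	-2
G2	2	0	0
G3	0	0	0
G4	0	-1	0
G5	0	0	1
G6	0	0	0
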