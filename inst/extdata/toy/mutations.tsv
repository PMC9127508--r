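sample	gene	chrom	pos	ref	alt	type	sift_score	sift_pred	polyphen_score	polyphen_pred	domains
S1	G1	1	100	C	T	missense	0.05	D	0.95	D	PF00870
S1	G4	1	10	A	G	silent	0.9	T	0.1	B	.
S1	G5	1	5	A	C	missense	0.5	T	0.6	P	.
S2	G1	1	150	G	A	missense	.	.	0.8	D	PF00870;PF00028
S2	G3	1	7	T	A	nonsense	0.0	D	0.99	D	.
S2	G2	1	50	A	G	missense	0.2	D	0.7	P	.
S3	G1	1	100	C	T	missense	0.1	D	0.9	D	PF00870
S3	G1	1	200	G	A	nonsense	0.02	D	0.97	D	.
S3	G6	1	9	C	G	frameshift_del	.	.	.	.	.
S3	G4	1	11	T	C	missense	0.8	T	0.2	B	.
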