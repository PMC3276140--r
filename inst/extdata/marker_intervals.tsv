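strain	trait	contig	left	right
106	Com	3	1565000	1827000
305	amyc	1	2988000	3730000
2261	do	7	>3475561	.
3562	Mb-1	7	.	<4255303
3246	fs-n	1	1860000	1940000
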