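n_keys	n_strains	n_cds_keys
25894	1	1885
16682	2	1168
8818	3	481
4968	4	284
3235	5	167
1586	6	69
640	7	39
453	8	25
347	9	17
108	10	2
56	11	4
25	12	0
22	13	0
14	14	1
15	15	1
13	16	1
19	17	2
57	18	15
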