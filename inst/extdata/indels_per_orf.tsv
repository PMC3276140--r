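n_orfs	n_indels
1352	1
495	2
198	3
96	4
55	5
31	6
19	7
9	8
3	9
4	10
3	11
0	12
4	13
1	23
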