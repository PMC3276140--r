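strain	nonsense
106	18
305	67
309	11
322	95
821	122
1211	19
1303	35
1363	137
2261	37
3114	31
3246	14
3562	78
3564	36
3566	27
3831	15
3921	84
7022	45
7035	13
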