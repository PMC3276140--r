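strain	unique_snps
821	73336
3114	29263
1363	21607
3562	16432
7022	15721
3921	9433
1303	9355
305	6653
3566	5306
3564	4612
3246	4253
322	3496
1211	3468
2261	3227
7035	2714
3831	1962
106	1033
309	704
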