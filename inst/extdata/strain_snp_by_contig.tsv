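strain	contig1	contig2	contig3	contig4	contig5	contig6	contig7	other_contigs
106	5044	947	3607	2250	853	391	9186	1301
305	38046	2537	8514	1019	26797	857	8075	4350
309	4943	2055	891	592	896	454	604	2839
322	29658	7256	28243	12754	24790	16428	22415	946
821	45205	12122	16891	41336	15980	30781	19517	6514
1211	4379	2207	4267	1635	1094	1608	3633	1670
1303	7227	13847	10817	4606	5237	12333	3341	1947
1363	43626	21549	19525	8625	32371	3402	17307	236
2261	1304	789	10200	3545	261	10966	15258	2516
3114	2725	2165	27516	1868	1614	1710	1731	1756
3246	7811	845	792	2606	6415	482	547	2035
3562	9178	4064	19381	28334	20810	13947	8024	2795
3564	5492	3142	1510	4691	16787	12046	1828	2485
3566	8701	5056	1402	9660	4716	1698	1570	4713
3831	2410	1584	6176	1187	2824	1177	5243	2360
3921	16641	2307	17416	9018	14521	5537	12038	2833
7022	32843	3897	1749	3105	11562	11989	10164	3682
7035	6040	1396	3145	3668	675	668	869	2026
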