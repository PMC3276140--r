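strain	total	unique	cds	nc	intron	splice_site	other
106	3607	136	294	2636	289	7	381
305	13335	816	1014	9492	1052	18	1759
309	1959	123	137	1466	151	3	202
322	15105	2001	701	11182	1236	22	1964
821	21224	6941	919	16066	1637	27	2575
1211	1494	100	103	1141	106	3	141
1303	6110	501	321	4746	413	7	623
1363	24952	5213	2091	17573	1997	31	3260
2261	7059	546	600	5143	584	6	726
3114	4211	3468	246	2971	369	6	619
3246	2310	89	124	1781	146	4	255
3562	13753	1920	741	10131	1119	19	1743
3564	4960	116	274	3747	387	8	544
3566	3714	471	199	2933	261	6	315
3831	2450	140	138	1922	168	4	218
3921	9743	979	581	7391	748	10	1013
7022	8907	918	471	6765	625	8	1038
7035	1869	93	134	1386	148	2	199
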