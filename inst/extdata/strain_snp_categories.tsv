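strain	total	nc	synonymous	nonsynonymous	utr3	utr5	intron	nonsense	pct_nc	pct_syn	pct_nonsyn	pct_nonsense
106	23579	14110	4536	2269	851	494	1143	18	59.84	32.15	9.62	0.08
305	90195	49883	18740	8417	4875	2560	4709	67	55.31	37.57	9.33	0.07
309	13274	9949	1725	667	321	144	414	11	74.95	17.34	5.02	0.08
322	142489	88879	24733	11525	6692	3112	6413	95	62.38	27.83	8.09	0.07
821	188346	112490	35810	17193	8458	4177	8825	122	59.73	31.83	9.13	0.06
1211	20493	16100	2263	1146	339	187	380	19	78.56	14.06	5.59	0.09
1303	59356	41212	8773	4330	1828	816	2119	35	69.43	21.29	7.29	0.06
1363	146641	71259	35955	15999	8535	4463	8685	137	48.59	50.46	10.91	0.09
2261	44839	25265	9894	4507	1772	911	2111	37	56.35	39.16	10.05	0.08
3114	41085	24550	9176	3186	1461	751	1626	31	59.75	37.38	7.75	0.08
3246	21533	14301	3405	1556	839	404	843	14	66.41	23.81	7.23	0.07
3562	106533	57767	22686	10480	5800	2830	5862	78	54.22	39.27	9.84	0.07
3564	47981	31886	7821	3702	1661	777	1737	36	66.46	24.53	7.72	0.08
3566	37516	29134	3962	1875	806	354	1198	27	77.66	13.6	5	0.07
3831	22961	17290	2563	1369	523	253	792	15	75.3	14.82	5.96	0.07
3921	80311	47446	16023	7557	3158	1605	3901	84	59.08	33.77	9.41	0.1
7022	78991	51944	12585	5843	3110	1602	3270	45	65.76	24.23	7.4	0.06
7035	18487	13174	2656	1160	472	241	686	13	71.26	20.16	6.27	0.07
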