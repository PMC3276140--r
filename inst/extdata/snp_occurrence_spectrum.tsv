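n_strains	n_keys
1	227988
2	115667
3	68186
4	40033
5	24418
6	13026
7	5285
8	3817
9	2912
10	769
11	559
12	68
13	49
14	33
15	43
16	48
17	42
18	96
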