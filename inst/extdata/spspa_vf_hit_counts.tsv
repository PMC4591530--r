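sample	total_hits	hits_per_1e5bp	iron	haemophilus_iron	vibrio
Sw14-1	971	12.7	126	47	51
Sw14-2	698	13.1	81	45	35
Sw14-3	579	14.2	65	26	28
Sw15-1	547	18.2	62	19	24
Sw15-2	994	16.0	86	22	44
Sw15-4	1292	19.4	154	24	69
Sw18-1	1045	21.0	71	25	69
Sw18-2	4815	22.7	317	108	373
Sw18-3	2362	24.3	217	64	143
Sw22-1	1941	16.6	181	74	127
Sw22-2	1415	16.8	108	43	91
Sw22-3	1565	16.6	129	32	83
Mad14	145	1.5	11	10	1
Mad15-1	92	0.6	7	6	1
Mad15-2	435	3.1	28	9	30
Mad18	138	1.0	6	0	3
MadBle18-1	464	6.2	31	5	26
MadBle18-2	1020	8.5	87	29	55
Mad22	344	2.4	24	11	21
MadBle22-1	171	0.8	5	5	8
MadBle22-2	197	2.3	21	2	16
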