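library_id	sample_id	replicate	day	habitat	health
4461594.3	Sw14	1	14	seawater	n/a
4463932.3	Sw14	2	14	seawater	n/a
4463933.3	Sw14	3	14	seawater	n/a
4463930.3	Sw15	1	15	seawater	n/a
4463929.3	Sw15	2	15	seawater	n/a
4463931.3	Sw15	4	15	seawater	n/a
4463927.3	Sw18	1	18	seawater	n/a
4468639.3	Sw18	2	18	seawater	n/a
4463928.3	Sw18	3	18	seawater	n/a
4461593.3	Sw22	1	22	seawater	n/a
4463926.3	Sw22	2	22	seawater	n/a
4463925.3	Sw22	3	22	seawater	n/a
4486661.3	Mad14	1	14	coral	healthy
4486662.3	Mad15	1	15	coral	healthy
4486663.3	Mad15	2	15	coral	healthy
4486664.3	Mad18	1	18	coral	healthy
4486665.3	MadBle18	1	18	coral	bleached
4486666.3	MadBle18	2	18	coral	bleached
4486669.3	Mad22	1	22	coral	healthy
4486667.3	MadBle22	1	22	coral	bleached
4486668.3	MadBle22	2	22	coral	bleached
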