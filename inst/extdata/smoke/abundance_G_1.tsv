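target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	123	45293.5920157708
g001.t2	864	864	48	19639.4978930172
g001.t3	777	777	36	16378.8862737132
g001.tg	924	924	0	0
g002.t1	948	948	195	72715.8624519939
g002.t2	762	762	64	29691.2094130653
g002.t3	768	768	46	21173.8336659091
g003.t1	729	729	232	112502.802745185
g003.t2	579	579	97	59223.770848373
g003.t3	612	612	35	20217.1301839883
g004.t1	978	978	229	82775.0616717962
g004.t2	819	819	94	40573.9077350245
g004.t3	822	822	31	13331.9219273766
g005.t1	762	762	322	149383.897359485
g005.t2	651	651	113	61362.1178408554
g005.t3	606	606	65	37917.8424667163
g006.t1	846	846	193	80647.2998585598
g006.t2	693	693	120	61214.0194068067
g006.t3	699	699	64	32367.2411627407
g006.tn	738	738	91	43590.1050796234
g002.tx	1038	1038	0	0
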