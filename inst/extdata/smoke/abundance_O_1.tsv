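target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	151	54452.4397614666
g001.t2	864	864	99	39667.3402235849
g001.t3	777	777	25	11138.6002733829
g001.tg	924	924	0	0
g002.t1	948	948	188	68653.2562672863
g002.t2	762	762	63	28621.8174268959
g002.t3	768	768	26	11719.8959751501
g003.t1	729	729	246	116820.539558571
g003.t2	579	579	118	70552.9329647936
g003.t3	612	612	72	40727.9642937343
g004.t1	978	978	157	55574.0985173705
g004.t2	819	819	80	33815.6480094497
g004.t3	822	822	68	28638.3982503387
g005.t1	762	762	246	111761.382333594
g005.t2	651	651	147	78171.4153379739
g005.t3	606	606	52	29705.8749469151
g006.t1	846	846	254	103938.150012024
g006.t2	693	693	139	69437.3590375859
g006.t3	699	699	60	29715.6821027246
g006.tn	738	738	36	16887.2047071581
g002.tx	1038	1038	0	0
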