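target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	115	45617.5789477441
g001.t2	864	864	49	21596.7281974827
g001.t3	777	777	38	18623.795870558
g001.tg	924	924	0	0
g002.t1	948	948	176	70698.4602734438
g002.t2	762	762	87	43478.0348478328
g002.t3	768	768	40	19833.7299772801
g003.t1	729	729	155	80967.3256685671
g003.t2	579	579	102	67085.2794257431
g003.t3	612	612	40	24889.3866381554
g004.t1	978	978	169	65804.1789675648
g004.t2	819	819	106	49286.4557384132
g004.t3	822	822	45	20847.1322388929
g005.t1	762	762	187	93452.7875464912
g005.t2	651	651	145	84818.9005479995
g005.t3	606	606	87	54670.4002542056
g006.t1	846	846	248	111631.546879216
g006.t2	693	693	121	66490.2185905007
g006.t3	699	699	66	35956.0838729747
g006.tn	738	738	47	24251.9755169343
g002.tx	1038	1038	0	0
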