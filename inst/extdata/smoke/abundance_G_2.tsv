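target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	215	77061.6503033781
g001.t2	864	864	97	38630.3880073781
g001.t3	777	777	42	18599.4177979241
g001.tg	924	924	0	0
g002.t1	948	948	257	93281.5737555168
g002.t2	762	762	84	37931.0961390735
g002.t3	768	768	42	18817.3797252435
g003.t1	729	729	228	107616.384460417
g003.t2	579	579	74	43976.861770912
g003.t3	612	612	40	22489.492108601
g004.t1	978	978	168	59107.3522657955
g004.t2	819	819	87	36551.6031083746
g004.t3	822	822	43	17999.801530716
g005.t1	762	762	253	114244.849085543
g005.t2	651	651	130	68712.1348755873
g005.t3	606	606	48	27254.59241676
g006.t1	846	846	215	87445.84431589
g006.t2	693	693	150	74478.1881518604
g006.t3	699	699	66	32489.1117757729
g006.tn	738	738	50	23312.2784052571
g002.tx	1038	1038	0	0
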