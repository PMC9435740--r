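target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	183	61268.5663729594
g001.t2	864	864	77	28644.0777821364
g001.t3	777	777	36	14891.5307849968
g001.tg	924	924	85	29566.8335346053
g002.t1	948	948	211	71537.2069153735
g002.t2	762	762	53	22355.2103112042
g002.t3	768	768	27	11299.5306835376
g003.t1	729	729	80	35271.2068890184
g003.t2	579	579	229	127120.262289716
g003.t3	612	612	27	14179.8032107138
g004.t1	978	978	189	62112.7576223907
g004.t2	819	819	72	28255.7250792246
g004.t3	822	822	54	21114.4514962454
g005.t1	762	762	361	152268.507968768
g005.t2	651	651	92	45421.8376273558
g005.t3	606	606	73	38717.5704829392
g006.t1	846	846	322	122332.927936088
g006.t2	693	693	88	40813.8251144356
g006.t3	699	699	44	20231.7459258254
g006.tn	738	738	71	30921.4498199306
g002.tx	1038	1038	70	21674.9721525362
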