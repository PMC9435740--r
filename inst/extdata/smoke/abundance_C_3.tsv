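target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	125	44046.4814997473
g001.t2	864	864	92	36020.2337597934
g001.t3	777	777	38	16543.790425851
g001.tg	924	924	0	0
g002.t1	948	948	190	67798.128485687
g002.t2	762	762	93	41285.7728955112
g002.t3	768	768	41	18059.0574148964
g003.t1	729	729	206	95589.9279164887
g003.t2	579	579	99	57840.1050326216
g003.t3	612	612	36	19898.6457598858
g004.t1	978	978	343	118639.062807663
g004.t2	819	819	12	4956.43923689464
g004.t3	822	822	6	2469.1750212997
g005.t1	762	762	382	169582.422000917
g005.t2	651	651	126	65472.9634680115
g005.t3	606	606	77	42982.3882833178
g006.t1	846	846	292	116757.538477628
g006.t2	693	693	84	41003.2700506739
g006.t3	699	699	46	22261.4320232199
g006.tn	738	738	41	18793.1654398922
g002.tx	1038	1038	0	0
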