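target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	251	85193.8071007355
g001.t2	864	864	87	32810.3639564586
g001.t3	777	777	35	14677.5160289843
g001.tg	924	924	0	0
g002.t1	948	948	244	83866.2118415632
g002.t2	762	762	97	41478.4291559248
g002.t3	768	768	19	8061.1670065437
g003.t1	729	729	181	80901.5019309527
g003.t2	579	579	88	49523.3079692982
g003.t3	612	612	35	18634.6894681712
g004.t1	978	978	152	50641.9326055261
g004.t2	819	819	93	37000.243703835
g004.t3	822	822	55	21802.0037364839
g005.t1	762	762	329	140684.568992776
g005.t2	651	651	169	84588.486386395
g005.t3	606	606	85	45703.7504070846
g006.t1	846	846	280	107843.309262608
g006.t2	693	693	86	40436.2389646995
g006.t3	699	699	57	26570.7135666333
g006.tn	738	738	67	29581.7579153268
g002.tx	1038	1038	0	0
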