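target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	217	71657.0706402984
g001.t2	864	864	82	30086.4300691473
g001.t3	777	777	52	21215.4805874164
g001.tg	924	924	0	0
g002.t1	948	948	220	73567.312796433
g002.t2	762	762	98	40770.0884516811
g002.t3	768	768	43	17749.1592023781
g003.t1	729	729	172	74794.8107952063
g003.t2	579	579	109	59678.5803570499
g003.t3	612	612	37	19165.5307757552
g004.t1	978	978	99	32089.7910418797
g004.t2	819	819	70	27094.721263022
g004.t3	822	822	42	16197.5012513978
g005.t1	762	762	455	189289.696382805
g005.t2	651	651	187	91060.7383277508
g005.t3	606	606	79	41326.1565402825
g006.t1	846	846	253	94802.7002490204
g006.t2	693	693	121	55350.6448658877
g006.t3	699	699	30	13605.503810187
g006.tn	738	738	71	30498.0825924015
g002.tx	1038	1038	0	0
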