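target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	127	47792.0736327097
g001.t2	864	864	116	48502.8918757159
g001.t3	777	777	26	12088.5918774251
g001.tg	924	924	0	0
g002.t1	948	948	294	112037.234310907
g002.t2	762	762	71	33660.9806229513
g002.t3	768	768	34	15993.4104676391
g003.t1	729	729	159	78793.9699436917
g003.t2	579	579	57	35564.7433014004
g003.t3	612	612	25	14757.4721731387
g004.t1	978	978	287	106014.782919377
g004.t2	819	819	4	1764.40985982142
g004.t3	822	822	2	878.985203889137
g005.t1	762	762	229	108568.514966984
g005.t2	651	651	173	96003.817130767
g005.t3	606	606	61	36364.7492519877
g006.t1	846	846	274	117004.775119115
g006.t2	693	693	105	54736.8058785508
g006.t3	699	699	60	31009.6926007241
g006.tn	738	738	99	48462.0988632048
g002.tx	1038	1038	0	0
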